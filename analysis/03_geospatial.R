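#!/usr/bin/env Rscript
# Stage 3: geospatial covariates.
# Derives, per identification (individual x daily encounter): water depth,
# Euclidean distance to shore, and barrier-aware water distance to the
# 200 m shelf-break isobath (signed: negative inshore). Also traces the
# shelf-width profile along the isobath (a point every 3 km) and builds
# the 5 km survey-effort fishnet from track lines and sighting positions.
# Outputs (results/): covariates.csv, shelf_width.csv, effort.asc

suppressPackageStartupMessages(library(podscape))

seascape <- read_esri_ascii("results/seascape.asc")
fields <- seascape_fields(seascape, level_m = 200)

rec <- read_encounters("results/encounters.csv", schema = list(
  date = "date", lat = "lat", lon = "lon", ids = "ids",
  group_size = "group_size", time = "time",
  encounter_id = "encounter_id", all_identified = "all_identified"))
daily <- consolidate_daily(rec)
# simulated records carry lon/lat; recover planar coordinates on the grid
cfg <- sim_config()
xy <- ll_to_planar(daily$lon, daily$lat, cfg$lon0, cfg$lat0)
daily$x <- xy$x; daily$y <- xy$y

cov <- encounter_covariates(daily, seascape, fields = fields)
write.csv(cov, "results/covariates.csv", row.names = FALSE)
cat(sprintf("Extracted covariates for %d identifications from %d encounters.\n",
            nrow(cov), nrow(daily)))

prof <- shelf_width_profile(seascape, spacing_m = 3000)
write.csv(prof, "results/shelf_width.csv", row.names = FALSE)
cat(sprintf("Shelf width along the 200 m isobath: %.1f-%.1f km (%d samples).\n",
            min(prof$width_km), max(prof$width_km), nrow(prof)))

tracks <- read.csv("results/tracks.csv")
eff <- effort_grid(tracks, daily[, c("x", "y")], cell_km = 5, resample_km = 3)
write_esri_ascii(seascape_grid(eff$counts + 0, eff$cell_size,
                               eff$xll, eff$yll), "results/effort.asc")
cat(sprintf("Effort fishnet: %d x %d cells of 5 km, %d effort points.\n",
            nrow(eff$counts), ncol(eff$counts), eff$n_points))
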