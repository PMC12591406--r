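#!/usr/bin/env Rscript
# Stage 5: cluster-wise habitat use.
# Labels the network clusters ecologically (the cluster nearer shore is
# "inner"), summarizes habitat covariates per cluster, compares them with
# rank-sum tests, fits 90% quantile habitat envelopes (inner: distance to
# shore; outer: |distance to shelf break|), maps envelope zones over the
# seascape, and tabulates mixed associations and prey composition.
# Outputs (results/): habitat_summaries.csv, rank_tests.json,
# envelope.json, zones.asc, mixed.json, prey.csv

suppressPackageStartupMessages(library(podscape))

cov <- read.csv("results/covariates.csv")
community <- jsonlite::read_json("results/community.json", simplifyVector = TRUE)
part <- unlist(community$partition)

shore_by_cl <- tapply(cov$dist_shore_km, part[cov$id], mean)
inner_cl <- names(which.min(shore_by_cl))
labels <- setNames(ifelse(part == inner_cl, "inner", "outer"), names(part))
cat(sprintf("Cluster sizes: inner %d, outer %d whales.\n",
            sum(labels == "inner"), sum(labels == "outer")))

vars <- c("dist_shore_km", "depth_m", "dist_shelf_km")
summaries <- do.call(rbind, lapply(vars, function(v)
  habitat_summary(cov, labels, v)))
write.csv(summaries, "results/habitat_summaries.csv", row.names = FALSE)
print(summaries)

lab_rows <- labels[cov$id]
tests <- lapply(vars, function(v)
  rank_sum_test(cov[[v]][lab_rows == "inner"], cov[[v]][lab_rows == "outer"]))
names(tests) <- vars
jsonlite::write_json(tests, "results/rank_tests.json", auto_unbox = TRUE,
                     digits = NA)

env <- fit_envelope(cov, labels, inner = "inner", outer = "outer", q = 0.90)
print(env)
jsonlite::write_json(unclass(env), "results/envelope.json",
                     auto_unbox = TRUE, digits = NA)

seascape <- read_esri_ascii("results/seascape.asc")
fields <- seascape_fields(seascape, level_m = 200)
zones <- envelope_zones(seascape, env, fields)
write_esri_ascii(seascape_grid(zones + 0, seascape$cell_size,
                               seascape$xll, seascape$yll), "results/zones.asc")
cat(sprintf("Envelope overlap occupies %d water cells (%.1f%% of water).\n",
            sum(zones == 3, na.rm = TRUE),
            100 * sum(zones == 3, na.rm = TRUE) / sum(!is.na(zones))))

rec <- read_encounters("results/encounters.csv", schema = list(
  date = "date", lat = "lat", lon = "lon", ids = "ids",
  group_size = "group_size", time = "time",
  encounter_id = "encounter_id", all_identified = "all_identified"))
daily <- consolidate_daily(rec)
mx <- mixed_associations(daily, labels)
cat(sprintf("Mixed associations: %d of %d encounters (%.2f%%).\n",
            mx$count, nrow(daily), 100 * mx$proportion))
jsonlite::write_json(list(count = mx$count, proportion = mx$proportion),
                     "results/mixed.json", auto_unbox = TRUE, digits = NA)

# prey composition needs the predation column from the raw simulator table
raw <- read.csv("results/encounters.csv")
daily$predations <- lapply(
  raw$predations[match(daily$encounter_id, raw$encounter_id)],
  function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(prey_species = vapply(parts, `[`, "", 1),
               count = as.integer(vapply(parts, `[`, "", 2)))
  })
prey <- prey_composition(daily, labels)
write.csv(prey, "results/prey.csv", row.names = FALSE)
print(prey)
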