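# Synthetic seascapes and two-subpopulation fission-fusion encounter data
# with known ground truth, so every pipeline stage is testable without
# field data.

#' Simulation configuration
#'
#' Defaults emulate the study system: a coastline whose continental shelf
#' narrows from ~50 km to ~12 km north to south; two latent subpopulations
#' of ~20 matrilines each (sizes 2-10, mode 4, plus a small fraction of
#' lone roving males); an inner subpopulation concentrated near shore
#' (lognormal distance-to-shore kernel, median ~2 km) and an outer one
#' centered on the 200 m shelf-break isobath (normal kernel, sd ~5 km);
#' daily fission-fusion grouping with a high within-subpopulation merge
#' probability and ~1% cross-subpopulation merges; and detection effort
#' biased toward nearshore waters.
#'
#' @param ... overrides for any default listed below.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # seascape geometry (planar meters; row 1 = north)
    n_rows = 160, n_cols = 120, cell_size = 1000,
    land_width_km = 8,
    shelf_km_north = 50, shelf_km_south = 12,
    shelf_slope_beyond = 25,      # m depth gained per km beyond the break
    canyons = list(),             # each: list(row_frac, width_km, dip_km)
    isobath_m = 200,
    # population
    n_matrilines = c(inner = 20, outer = 20),
    size_probs = c(`2` = 0.18, `3` = 0.22, `4` = 0.27, `5` = 0.13,
                   `6` = 0.08, `7` = 0.05, `8` = 0.04, `9` = 0.02,
                   `10` = 0.01),
    rove_frac = 0.1,              # lone roving-male units per subpopulation
    # daily grouping
    n_days = 365,
    start_date = as.Date("2020-01-01"),
    p_within = 0.7, p_between = 0.005,
    p_absent = 0.2,               # daily temporary-separation probability
    # spatial kernels (km)
    inner_meanlog = log(2), inner_sdlog = 0.8,
    outer_sd = 5,
    # detection / effort
    detect_base = 0.2, effort_nearshore_km = 10,
    effort_offshore_factor = 0.6,
    p_resight = 0.15,
    # predation
    pred_rate = 0.1,
    prey_inner = c(harbor_seal = 0.64, harbor_porpoise = 0.21,
                   steller_sea_lion = 0.09, california_sea_lion = 0.03,
                   other = 0.03),
    prey_outer = c(california_sea_lion = 0.49, gray_whale_calf = 0.20,
                   dolphin = 0.08, northern_elephant_seal = 0.07,
                   other = 0.16),
    # survey tracks for the effort grid
    n_tracks = 40,
    # lon/lat reference so emitted records carry valid coordinates
    lon0 = -126, lat0 = 47
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("sim_config", "list"))
}

#' Construct a synthetic seascape
#'
#' A coastline runs along the grid's east edge; elevation decreases
#' seaward, crossing -200 m at a per-row offshore distance that
#' interpolates linearly from \code{shelf_km_north} (row 1) to
#' \code{shelf_km_south}, with optional canyon incisions (Gaussian dips in
#' the local shelf-break distance). Deterministic: no randomness is used.
#'
#' @param config a [sim_config()].
#' @return a \code{seascape_grid}.
#' @export
make_seascape <- function(config = sim_config()) {
  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size
  coast_x <- nc * cs - config$land_width_km * 1000
  f <- if (nr > 1) (seq_len(nr) - 1) / (nr - 1) else 0
  d_km <- config$shelf_km_north + (config$shelf_km_south - config$shelf_km_north) * f
  for (cy in config$canyons) {
    r0 <- cy$row_frac * (nr - 1) + 1
    d_km <- d_km - cy$dip_km * exp(-((seq_len(nr) - r0) / cy$width_km)^2)
  }
  d_km <- pmax(d_km, 2)
  if (any(d_km * 1000 >= coast_x))
    stop("shelf-break distance exceeds the grid's water width")
  xs <- (seq_len(nc) - 0.5) * cs
  elev <- matrix(10, nr, nc)
  for (r in seq_len(nr)) {
    dist_m <- coast_x - xs                # distance seaward of the coast
    water <- dist_m > 0
    d <- d_km[r] * 1000
    depth <- ifelse(dist_m <= d, config$isobath_m * dist_m / d,
                    config$isobath_m +
                      config$shelf_slope_beyond * (dist_m - d) / 1000)
    elev[r, water] <- -depth[water]
  }
  seascape_grid(elev, cs, xll = 0, yll = 0, crs = "synthetic-planar")
}

#' Simulate the study population
#'
#' Draws matrilines for each subpopulation from the configured size
#' distribution (2-10 individuals, mode 4), plus a fraction of lone
#' roving-male units. Inner-coast individuals get "T"-style catalog ids,
#' outer-coast individuals "OCT"-style ids.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with \code{registry} (data.frame: id, matriline_id, subpop,
#'   sex_class) and \code{truth} (named subpop and matriline vectors).
#' @export
simulate_population <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  sizes_from <- as.integer(names(config$size_probs))
  rows <- list()
  for (sp in c("inner", "outer")) {
    prefix <- if (sp == "inner") "T" else "OCT"
    n_mat <- config$n_matrilines[[sp]]
    n_rove <- round(config$rove_frac * n_mat)
    sizes <- sample(sizes_from, n_mat, replace = TRUE, prob = config$size_probs)
    for (m in seq_len(n_mat)) {
      mat_id <- sprintf("%s%03d", prefix, m)
      for (k in seq_len(sizes[m])) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(mat_id, LETTERS[k]), matriline_id = mat_id,
          subpop = sp,
          sex_class = if (k == 1) "female" else
            sample(c("female", "male", "unknown"), 1),
          stringsAsFactors = FALSE)
      }
    }
    for (m in seq_len(n_rove)) {
      mat_id <- sprintf("%s%03d", prefix, 100 + m)
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(mat_id, "A"), matriline_id = mat_id, subpop = sp,
        sex_class = "male", stringsAsFactors = FALSE)
    }
  }
  registry <- do.call(rbind, rows)
  truth <- list(
    subpop = setNames(registry$subpop, registry$id),
    matriline = setNames(registry$matriline_id, registry$id)
  )
  list(registry = registry, truth = truth)
}

#' Simulate daily fission-fusion encounters over a seascape
#'
#' Each day, matrilines form groups by single-pass sequential merging in
#' random order: a matriline joins a randomly chosen existing group with
#' probability \code{p_within} if the group was founded by its own
#' subpopulation, \code{p_between} otherwise, and founds a new group if it
#' joins none. Every individual therefore belongs to exactly one group per
#' day. Each group draws a location from its subpopulation's spatial
#' kernel over water cells (inner keyed to distance-to-shore, outer to
#' signed shelf-break distance) and is detected with a nearshore-weighted
#' probability. Detected groups are emitted as fully identified encounter
#' records; occasional same-day resight rows (full or subset) exercise the
#' daily consolidation. Survey tracks are emitted for effort grids.
#'
#' @param registry,truth from [simulate_population()].
#' @param seascape grid from [make_seascape()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param fields optional precomputed [seascape_fields()].
#' @return list with \code{encounters} (encounter data.frame with planar
#'   x/y, lon/lat, individuals and predations list columns), \code{tracks}
#'   (track_id, order, x, y) and \code{truth}.
#' @export
simulate_encounters <- function(registry, truth, seascape,
                                config = sim_config(), seed = 1,
                                fields = NULL) {
  set.seed(seed)
  if (is.null(fields)) fields <- seascape_fields(seascape, config$isobath_m)
  nr <- nrow(fields$land)
  wcells <- which(!fields$land)
  shore_v <- fields$shore_km[wcells]
  signed_v <- fields$signed_shelf_km[wcells]
  w_inner <- stats::dlnorm(shore_v, config$inner_meanlog, config$inner_sdlog)
  w_outer <- stats::dnorm(signed_v, 0, config$outer_sd)
  w_inner[!is.finite(w_inner)] <- 0
  w_outer[!is.finite(w_outer)] <- 0
  if (sum(w_inner) == 0 || sum(w_outer) == 0)
    stop("spatial kernels incompatible with seascape: no reachable water")
  p_detect <- config$detect_base *
    ifelse(shore_v <= config$effort_nearshore_km, 1,
           config$effort_offshore_factor)

  mats <- split(registry$id, registry$matriline_id)
  mat_ids <- names(mats)
  mat_subpop <- vapply(mats, function(ids) truth$subpop[[ids[1]]], character(1))
  n_mat <- length(mat_ids)
  cs <- seascape$cell_size
  all_ids <- registry$id
  matriarch <- match(vapply(mats, `[`, character(1), 1), all_ids)

  enc <- list()
  eid <- 0L
  for (day in seq_len(config$n_days)) {
    ord <- sample.int(n_mat)
    group_of <- integer(n_mat)       # group index per matriline
    founder_sp <- character(0)
    for (m in ord) {
      same <- which(founder_sp == mat_subpop[m])
      other <- which(founder_sp != mat_subpop[m])
      joined <- FALSE
      if (length(other) && stats::runif(1) < config$p_between) {
        group_of[m] <- other[sample.int(length(other), 1)]
        joined <- TRUE
      } else if (length(same) && stats::runif(1) < config$p_within) {
        group_of[m] <- same[sample.int(length(same), 1)]
        joined <- TRUE
      }
      if (!joined) {
        founder_sp <- c(founder_sp, mat_subpop[m])
        group_of[m] <- length(founder_sp)
      }
    }
    n_groups <- length(founder_sp)
    # one location draw per group from the founder subpopulation's kernel
    cell_idx <- integer(n_groups)
    is_in <- founder_sp == "inner"
    if (any(is_in))
      cell_idx[is_in] <- sample(seq_along(wcells), sum(is_in),
                                replace = TRUE, prob = w_inner)
    if (any(!is_in))
      cell_idx[!is_in] <- sample(seq_along(wcells), sum(!is_in),
                                 replace = TRUE, prob = w_outer)
    # daily temporary separation: some members roam away from their matriline
    present <- stats::runif(length(all_ids)) >= config$p_absent
    present[matriarch] <- TRUE
    detected <- stats::runif(n_groups) < p_detect[cell_idx]
    for (g in which(detected)) {
      members <- unlist(mats[group_of == g], use.names = FALSE)
      members <- members[present[match(members, all_ids)]]
      if (length(members) == 0) next
      lin <- wcells[cell_idx[g]]
      row <- ((lin - 1L) %% nr) + 1L
      col <- ((lin - 1L) %/% nr) + 1L
      ctr <- .cell_xy(seascape, row, col)
      x <- ctr$x + stats::runif(1, -0.49, 0.49) * cs
      y <- ctr$y + stats::runif(1, -0.49, 0.49) * cs
      hh <- sample(7:15, 1)
      pred <- NULL
      if (stats::runif(1) < config$pred_rate) {
        tab <- if (founder_sp[g] == "inner") config$prey_inner else config$prey_outer
        pred <- data.frame(
          prey_species = sample(names(tab), 1, prob = tab),
          count = 1L, stringsAsFactors = FALSE)
      }
      eid <- eid + 1L
      enc[[length(enc) + 1L]] <- list(
        encounter_id = sprintf("E%05d", eid),
        date = config$start_date + day - 1L,
        time = sprintf("%02d:%02d", hh, sample(0:59, 1)),
        x = x, y = y, subpop = founder_sp[g],
        individuals = sort(members), predations = pred)
      # same-day resight by another observer: full or subset of the group
      if (stats::runif(1) < config$p_resight) {
        res_ids <- sort(members)
        if (length(members) > 1 && stats::runif(1) < 0.5)
          res_ids <- sort(sample(members, length(members) - 1))
        eid <- eid + 1L
        enc[[length(enc) + 1L]] <- list(
          encounter_id = sprintf("E%05d", eid),
          date = config$start_date + day - 1L,
          time = sprintf("%02d:%02d", hh + sample(1:4, 1), sample(0:59, 1)),
          x = x + stats::runif(1, -200, 200),
          y = y + stats::runif(1, -200, 200),
          subpop = founder_sp[g],
          individuals = res_ids, predations = NULL)
      }
    }
  }
  if (length(enc) == 0) stop("no encounters simulated; raise detect_base")
  encounters <- data.frame(
    encounter_id = vapply(enc, `[[`, character(1), "encounter_id"),
    date = as.Date(vapply(enc, function(e) as.character(e$date), character(1))),
    time = vapply(enc, `[[`, character(1), "time"),
    x = vapply(enc, `[[`, numeric(1), "x"),
    y = vapply(enc, `[[`, numeric(1), "y"),
    source = "small_vessel",
    stringsAsFactors = FALSE)
  ll <- planar_to_ll(encounters$x, encounters$y, config$lon0, config$lat0)
  encounters$lon <- ll$lon
  encounters$lat <- ll$lat
  encounters$individuals <- lapply(enc, `[[`, "individuals")
  encounters$group_size <- lengths(encounters$individuals)
  encounters$all_identified <- TRUE
  encounters$predations <- lapply(enc, `[[`, "predations")
  encounters$true_subpop <- vapply(enc, `[[`, character(1), "subpop")

  # east-west survey transects across the shelf at random northings
  coast_x <- config$n_cols * cs - config$land_width_km * 1000
  tracks <- do.call(rbind, lapply(seq_len(config$n_tracks), function(t) {
    y <- stats::runif(1, 0, nr * cs)
    data.frame(track_id = sprintf("trk%03d", t), order = 1:2,
               x = c(1000, coast_x - 1000), y = y,
               stringsAsFactors = FALSE)
  }))
  list(encounters = encounters, tracks = tracks, truth = truth)
}

#' Write a simulated encounter table as CSV
#'
#' Serializes the list columns (ids joined by ";", predations as
#' "species:count" pairs joined by "|") so the file round-trips through
#' [read_encounters()].
#'
#' @param encounters encounter data.frame from [simulate_encounters()].
#' @param path output CSV path.
#' @export
write_encounters_csv <- function(encounters, path) {
  df <- encounters[, c("encounter_id", "date", "time", "lon", "lat",
                       "source", "group_size", "all_identified")]
  df$ids <- vapply(encounters$individuals, paste, character(1), collapse = ";")
  df$predations <- vapply(encounters$predations, function(p) {
    if (is.null(p) || nrow(p) == 0) return("")
    paste(paste0(p$prey_species, ":", p$count), collapse = "|")
  }, character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
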