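#' Run the full subpopulation-delineation pipeline on simulated data
#'
#' Executes the whole analysis chain end to end with known ground truth:
#' simulate a seascape, population, and encounter history; consolidate to
#' daily encounters; apply the complete-identification and minimum-sightings
#' filters; build the simple-ratio association matrix; cluster it and select
#' the modularity-maximizing partition; derive habitat covariates per
#' identification; regress associations on habitat similarity with MRQAP;
#' and summarize cluster-wise habitat use, quantile envelopes, mixed
#' associations, and prey composition. Deterministic given \code{seed}.
#'
#' @param config a [sim_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @param min_sightings network inclusion threshold (default 3).
#' @param n_perm MRQAP permutations (default 1000).
#' @param q envelope quantile (default 0.90).
#' @param do_geo run the geospatial/habitat stages (default TRUE); when
#'   FALSE only the social-network stages run (faster).
#' @param do_mrqap run the MRQAP stage (default \code{do_geo}).
#' @param include_matriline add the matriline same-group predictor to the
#'   MRQAP (default FALSE, matching the reported model).
#' @return a list report: headline numbers plus the stage objects
#'   (\code{assoc}, \code{community}, \code{covariates}, \code{mrqap},
#'   \code{envelope}, \code{summaries}, ...).
#' @export
run_pipeline <- function(config = sim_config(), seed = 1, min_sightings = 3,
                         n_perm = 1000, q = 0.90, do_geo = TRUE,
                         do_mrqap = do_geo, include_matriline = FALSE) {
  seascape <- make_seascape(config)
  fields <- seascape_fields(seascape, config$isobath_m)
  pop <- simulate_population(config, seed = seed)
  sim <- simulate_encounters(pop$registry, pop$truth, seascape, config,
                             seed = seed + 1L, fields = fields)

  daily <- consolidate_daily(sim$encounters)
  filt <- filter_for_network(daily, min_sightings = min_sightings)
  counts <- pair_counts(filt$records, filt$retained_ids)
  assoc <- sri_matrix(counts)
  dend <- average_linkage(assoc)
  community <- best_partition(dend, assoc)

  truth_labels <- pop$truth$subpop[assoc$ids]
  report <- list(
    seed = seed,
    n_simulated = nrow(pop$registry),
    n_encounters = nrow(daily),
    n_retained = length(filt$retained_ids),
    n_excluded = length(filt$excluded_ids),
    mean_group_size = mean(daily$group_size),
    ccc = community$ccc,
    q_max = community$q_max,
    k = community$k,
    cluster_sizes = as.integer(table(community$partition)),
    ari = adjusted_rand(community$partition, truth_labels),
    assoc = assoc, dend = dend, community = community,
    seascape = seascape, fields = fields, truth = pop$truth,
    daily = daily, filter = filt
  )

  if (!do_geo) return(report)

  cov <- encounter_covariates(daily, seascape, config$isobath_m,
                              fields = fields, ids = assoc$ids)
  # label clusters ecologically: the cluster nearer shore is "inner"
  part <- community$partition[assoc$ids]
  shore_by_cl <- tapply(cov$dist_shore_km, part[cov$id], mean)
  inner_cl <- as.integer(names(which.min(shore_by_cl)))
  labels <- ifelse(part == inner_cl, "inner", "outer")
  names(labels) <- names(part)

  summaries <- do.call(rbind, lapply(
    c("dist_shore_km", "depth_m", "dist_shelf_km"),
    function(v) habitat_summary(cov, labels, v)))
  tests <- lapply(c("dist_shore_km", "depth_m", "dist_shelf_km"), function(v) {
    lab <- labels[cov$id]
    rank_sum_test(cov[[v]][lab == "inner"], cov[[v]][lab == "outer"])
  })
  names(tests) <- c("dist_shore_km", "depth_m", "dist_shelf_km")

  envelope <- if (community$k >= 2)
    fit_envelope(cov, labels, inner = "inner", outer = "outer", q = q)
  else NULL
  mixed <- mixed_associations(daily, labels)

  report <- c(report, list(
    covariates = cov, labels = labels,
    summaries = summaries, rank_tests = tests,
    envelope = envelope, mixed = mixed,
    prey = prey_composition(daily, labels),
    inner_mean_shore_km = unname(shore_by_cl[as.character(inner_cl)]),
    mixed_count = mixed$count,
    mixed_proportion = mixed$proportion
  ))

  if (do_mrqap) {
    mean_by_id <- function(v) tapply(v, cov$id, mean)[assoc$ids]
    preds <- list(
      build_predictor(mean_by_id(cov$depth_m), name = "depth_similarity"),
      build_predictor(mean_by_id(cov$dist_shore_km), name = "shore_similarity"),
      build_predictor(mean_by_id(cov$dist_shelf_km), name = "shelf_similarity"),
      geo_proximity_predictor(mean_by_id(cov$x), mean_by_id(cov$y),
                              planar = TRUE)
    )
    if (include_matriline)
      preds <- c(preds, list(build_predictor(
        pop$truth$matriline[assoc$ids],
        method = "same_group_indicator", name = "same_matriline")))
    report$mrqap <- fit_mrqap(assoc, preds, n_perm = n_perm, seed = seed)
  }
  report
}

#' Write a machine-readable run report
#'
#' Serializes the headline numbers of a [run_pipeline()] report (not the
#' large stage objects) as JSON; every number is re-derivable from the
#' stage outputs.
#'
#' @param report list from [run_pipeline()].
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  keep <- list(
    seed = report$seed,
    n_simulated = report$n_simulated,
    n_encounters = report$n_encounters,
    n_retained = report$n_retained,
    n_excluded = report$n_excluded,
    mean_group_size = report$mean_group_size,
    ccc = report$ccc,
    q_max = report$q_max,
    k = report$k,
    cluster_sizes = report$cluster_sizes,
    ari = report$ari
  )
  if (!is.null(report$mrqap)) {
    keep$mrqap <- list(beta = as.list(report$mrqap$beta),
                       adj_r2 = report$mrqap$adj_r2,
                       f_stat = report$mrqap$f_stat,
                       p_perm = as.list(report$mrqap$p_perm),
                       n_perm = report$mrqap$n_perm)
  }
  if (!is.null(report$envelope)) {
    keep$envelope <- list(
      q = report$envelope$q,
      inner_shore_threshold_km = report$envelope$inner_shore_threshold_km,
      outer_shelf_threshold_km = report$envelope$outer_shelf_threshold_km,
      coverage_inner = report$envelope$coverage_inner,
      coverage_outer = report$envelope$coverage_outer)
  }
  if (!is.null(report$mixed))
    keep$mixed <- list(count = report$mixed$count,
                       proportion = report$mixed$proportion)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
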