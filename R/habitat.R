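# Cluster-wise habitat summaries, nonparametric comparisons, quantile
# habitat envelopes, and mixed-association / prey tabulations. The unit of
# analysis throughout is the identification (one individual in one daily
# encounter), matching how per-cluster sample sizes are accounted.

#' Per-cluster habitat summaries
#'
#' Mean, standard error (sd / sqrt(n)), range and n of a covariate per
#' cluster, over identifications.
#'
#' @param covariates identification table from [encounter_covariates()].
#' @param partition named cluster labels (individual id -> label).
#' @param variable covariate column name (e.g., "dist_shore_km").
#' @return data.frame with one row per non-empty cluster: \code{cluster},
#'   \code{variable}, \code{mean}, \code{se} (0 with \code{se_defined} FALSE
#'   when n = 1), \code{min}, \code{max}, \code{n}.
#' @export
habitat_summary <- function(covariates, partition, variable) {
  stopifnot(variable %in% names(covariates))
  lab <- partition[covariates$id]
  keep <- !is.na(lab)
  if (!all(keep)) covariates <- covariates[keep, , drop = FALSE]
  lab <- lab[keep]
  levels_all <- unique(partition)
  empty <- setdiff(levels_all, unique(lab))
  if (length(empty))
    warning("empty cluster(s) omitted: ", paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(split(covariates[[variable]], lab), function(v) {
    n <- length(v)
    data.frame(mean = mean(v),
               se = if (n > 1) stats::sd(v) / sqrt(n) else 0,
               se_defined = n > 1,
               min = min(v), max = max(v), n = n)
  }))
  data.frame(cluster = rownames(out), variable = variable, out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. For small samples
#' (|x| + |y| <= 12) the p-value is computed by exhaustive enumeration of
#' all C(N, m) assignments of the pooled (mid)ranks; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Returns both the Mann-Whitney U of the first sample and the
#' rank-sum W.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with \code{U}, \code{W} (rank sum of x), \code{p} and
#'   \code{method} ("exact" or "normal").
#' @export
rank_sum_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    r <- rank(pooled)
    W <- sum(r[seq_len(m)])
    return(list(U = W - m * (m + 1) / 2, W = W, p = 1, method = "degenerate"))
  }
  r <- rank(pooled)  # midranks
  W <- sum(r[seq_len(m)])
  U <- W - m * (m + 1) / 2
  mu <- m * n / 2
  if (N <= 12) {
    combos <- utils::combn(N, m)
    Us <- colSums(matrix(r[combos], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, W = W, p = p, method = "exact"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- m * n / 12 * ((N + 1) - tie_term)
  z <- (abs(U - mu) - 0.5) / sqrt(v)
  z <- max(z, 0)
  list(U = U, W = W, p = min(1, 2 * stats::pnorm(-z)), method = "normal")
}

#' Quantile habitat envelope
#'
#' The habitat envelope of each subpopulation is the empirical q-quantile
#' (linear interpolation between order statistics, R's default type 7) of
#' its habitat metric: distance to shore for the inner cluster, absolute
#' signed distance to the shelf break for the outer cluster. For distinct
#' values the in-sample coverage is floor((n-1)q + 1)/n, within 1/n of q on
#' either side; tied values (identifications sharing an encounter) can only
#' raise it.
#'
#' @param covariates identification table from [encounter_covariates()].
#' @param partition named cluster labels.
#' @param inner,outer labels of the nearshore and shelf-break clusters.
#' @param q envelope quantile in (0, 1) (default 0.90).
#' @return object of class \code{envelope_model}: list with
#'   \code{inner_shore_threshold_km}, \code{outer_shelf_threshold_km},
#'   \code{q}, coverage fractions and fitting n's.
#' @export
fit_envelope <- function(covariates, partition, inner, outer, q = 0.90) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  lab <- partition[covariates$id]
  v_in <- covariates$dist_shore_km[!is.na(lab) & lab == inner]
  v_out <- abs(covariates$signed_shelf_km[!is.na(lab) & lab == outer])
  if (length(v_in) == 0 || length(v_out) == 0)
    stop("both clusters must have identifications to fit an envelope")
  thr_in <- unname(stats::quantile(v_in, q, type = 7))
  thr_out <- unname(stats::quantile(v_out, q, type = 7))
  structure(list(
    inner_shore_threshold_km = thr_in,
    outer_shelf_threshold_km = thr_out,
    q = q,
    coverage_inner = mean(v_in <= thr_in),
    coverage_outer = mean(v_out <= thr_out),
    n_inner = length(v_in), n_outer = length(v_out)
  ), class = "envelope_model")
}

#' @export
print.envelope_model <- function(x, ...) {
  cat(sprintf(
    "%.0f%% habitat envelopes: inner within %.2f km of shore (coverage %.3f, n=%d);\n  outer within %.2f km of the shelf break (coverage %.3f, n=%d)\n",
    100 * x$q, x$inner_shore_threshold_km, x$coverage_inner, x$n_inner,
    x$outer_shelf_threshold_km, x$coverage_outer, x$n_outer))
  invisible(x)
}

#' Envelope zone raster
#'
#' Labels every water cell of the grid by which fitted envelope(s) it falls
#' in: 1 = inner only (within the shore-distance threshold), 2 = outer only
#' (within the shelf-break threshold), 3 = overlap, 0 = neither; land is NA.
#'
#' @param grid a \code{seascape_grid}.
#' @param envelope an \code{envelope_model}.
#' @param fields optional precomputed [seascape_fields()].
#' @return integer matrix of zone codes (same shape as the grid).
#' @export
envelope_zones <- function(grid, envelope, fields = NULL) {
  stopifnot(inherits(envelope, "envelope_model"))
  if (is.null(fields)) fields <- seascape_fields(grid)
  inner <- fields$shore_km <= envelope$inner_shore_threshold_km
  outer <- abs(fields$signed_shelf_km) <= envelope$outer_shelf_threshold_km
  zone <- matrix(0L, nrow(fields$land), ncol(fields$land))
  zone[inner & !outer] <- 1L
  zone[outer & !inner] <- 2L
  zone[inner & outer] <- 3L
  zone[fields$land] <- NA_integer_
  zone
}

#' Mixed-association tabulation
#'
#' An encounter is a mixed association when the individuals identified in
#' it span both clusters.
#'
#' @param records daily-consolidated encounter data.frame.
#' @param partition named cluster labels (individuals absent from the
#'   partition are ignored).
#' @return list with \code{count}, \code{proportion} (over all encounters
#'   given), and \code{roster} (per encounter: counts per cluster and a
#'   \code{mixed} flag).
#' @export
mixed_associations <- function(records, partition) {
  labs <- sort(unique(partition))
  per <- vapply(records$individuals, function(ids) {
    l <- partition[ids]
    vapply(labs, function(lv) sum(l == lv, na.rm = TRUE), numeric(1))
  }, numeric(length(labs)))
  per <- t(matrix(per, nrow = length(labs)))
  colnames(per) <- paste0("n_", labs)
  mixed <- rowSums(per > 0) >= 2
  roster <- data.frame(encounter_id = records$encounter_id, per,
                       mixed = mixed, stringsAsFactors = FALSE)
  list(count = sum(mixed),
       proportion = if (nrow(records)) sum(mixed) / nrow(records) else 0,
       roster = roster)
}

#' Prey composition per cluster
#'
#' Tabulates recorded predation events by prey species within each cluster.
#' Each encounter's events are attributed to the majority cluster of its
#' identified individuals (ties or no partitioned members -> "unclassified").
#'
#' @param records encounter data.frame with a \code{predations} list column
#'   (each element a data.frame with \code{prey_species}, \code{count}, or
#'   NULL).
#' @param partition named cluster labels.
#' @return data.frame with \code{cluster}, \code{prey_species},
#'   \code{events}, \code{percent} (summing to 100 within each cluster).
#' @export
prey_composition <- function(records, partition) {
  if (!"predations" %in% names(records))
    stop("records carry no predation records")
  rows <- list()
  for (i in seq_len(nrow(records))) {
    pred <- records$predations[[i]]
    if (is.null(pred) || nrow(pred) == 0) next
    l <- partition[records$individuals[[i]]]
    l <- l[!is.na(l)]
    cl <- if (length(l) == 0) "unclassified" else {
      tab <- sort(table(l), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] == tab[2]) "unclassified" else names(tab)[1]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, prey_species = pred$prey_species,
      events = pred$count, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    warning("no predation events recorded")
    return(data.frame(cluster = character(0), prey_species = character(0),
                      events = numeric(0), percent = numeric(0)))
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(events ~ cluster + prey_species, df, sum)
  totals <- tapply(agg$events, agg$cluster, sum)
  agg$percent <- 100 * agg$events / as.numeric(totals[agg$cluster])
  agg[order(agg$cluster, -agg$events), , drop = FALSE]
}
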