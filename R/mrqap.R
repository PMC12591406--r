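#' Build a pairwise predictor matrix from per-individual values
#'
#' Habitat-similarity predictors are built from one summary value per
#' individual (typically the mean of its per-identification covariate):
#' M[i, j] = -|v_i - v_j|, z-scored over the off-diagonal entries so that
#' larger values mean more similar habitat and coefficients are comparable
#' across predictors. \code{same_group_indicator} instead yields 1 when two
#' individuals share a matriline, 0 otherwise.
#'
#' @param values named numeric vector (one value per individual) for
#'   \code{neg_abs_diff_z}; named group labels for
#'   \code{same_group_indicator}.
#' @param method construction rule.
#' @param name label carried into the regression output.
#' @return object of class \code{predictor_matrix}: list with \code{name},
#'   \code{values} (symmetric matrix, zero diagonal) and \code{ids}.
#' @export
build_predictor <- function(values, method = c("neg_abs_diff_z",
                                               "same_group_indicator"),
                            name = deparse(substitute(values))) {
  method <- match.arg(method)
  ids <- names(values)
  if (is.null(ids)) stop("values must be named by individual id")
  if (method == "neg_abs_diff_z") {
    v <- as.numeric(values)
    if (any(!is.finite(v))) stop("non-finite covariate values")
    M <- -abs(outer(v, v, "-"))
    M <- .zscore_offdiag(M, name)
  } else {
    M <- (outer(values, values, "==")) * 1
    diag(M) <- 0
    off <- M[row(M) != col(M)]
    if (stats::sd(off) == 0)
      stop("constant predictor '", name, "': same-group indicator has no variance")
  }
  dimnames(M) <- list(ids, ids)
  structure(list(name = name, values = M, ids = ids),
            class = "predictor_matrix")
}

# z-score the off-diagonal entries of a symmetric matrix; zero diagonal.
.zscore_offdiag <- function(M, name = "predictor") {
  off <- row(M) != col(M)
  v <- M[off]
  if (stats::sd(v) == 0)
    stop("constant predictor '", name, "': zero variance across pairs")
  M[off] <- (v - mean(v)) / stats::sd(v)
  diag(M) <- 0
  M
}

#' Geographic-proximity predictor from encounter positions
#'
#' One predictor matrix for latitude/longitude jointly: the negative
#' pairwise distance between individuals' mean encounter positions,
#' z-scored (higher = geographically closer). Distances are great-circle
#' (haversine) for lon/lat input or Euclidean for planar input.
#'
#' @param lon,lat mean position per individual (named vectors); for
#'   \code{planar = TRUE} these are x and y in meters.
#' @param planar use Euclidean distance on planar coordinates.
#' @param name predictor label.
#' @return a \code{predictor_matrix}.
#' @export
geo_proximity_predictor <- function(lon, lat, planar = FALSE,
                                    name = "geo_proximity") {
  ids <- names(lon)
  if (is.null(ids) || !identical(ids, names(lat)))
    stop("lon and lat must be named identically by individual id")
  D <- if (planar) {
    sqrt(outer(lon, lon, "-")^2 + outer(lat, lat, "-")^2)
  } else {
    .haversine_matrix(lon, lat)
  }
  M <- .zscore_offdiag(-D, name)
  dimnames(M) <- list(ids, ids)
  structure(list(name = name, values = M, ids = ids),
            class = "predictor_matrix")
}

#' MRQAP: matrix regression with QAP permutation inference
#'
#' Regresses the association matrix on pairwise predictor matrices by OLS on
#' the vectorized off-diagonal entries (all n(n-1) ordered dyads), and
#' assesses significance against a null distribution built by QAP
#' permutation of the response: rows and columns of Y are relabeled
#' simultaneously by a fresh random permutation per replicate, preserving
#' the network's internal dependence. Two-tailed permutation p-values use
#' the +1 correction: p = (1 + #\{|beta*| >= |beta_hat|\}) / (1 + n_perm).
#'
#' @param Y an \code{association_matrix} or plain symmetric matrix.
#' @param Xs list of \code{predictor_matrix} objects (or plain matrices)
#'   sharing Y's id order.
#' @param n_perm number of QAP permutations (default 1000).
#' @param seed integer seed making the permutation null reproducible.
#' @return object of class \code{mrqap_result}: list with \code{beta}
#'   (named, intercept first), \code{adj_r2}, \code{f_stat}, \code{df},
#'   \code{p_perm} (per predictor), \code{n_perm}, \code{seed}, \code{n},
#'   and \code{collinear} flag.
#' @export
fit_mrqap <- function(Y, Xs, n_perm = 1000, seed = NULL) {
  Ym <- if (inherits(Y, "association_matrix")) Y$sri else Y
  ids <- rownames(Ym)
  n <- nrow(Ym)
  if (n < 5) stop("need at least 5 individuals for MRQAP")
  if (!is.list(Xs) || length(Xs) == 0) stop("Xs must be a non-empty list")
  Xmats <- lapply(Xs, function(x) if (inherits(x, "predictor_matrix")) x$values else x)
  xnames <- vapply(seq_along(Xs), function(i) {
    if (inherits(Xs[[i]], "predictor_matrix")) Xs[[i]]$name
    else if (!is.null(names(Xs)[i]) && nzchar(names(Xs)[i])) names(Xs)[i]
    else paste0("X", i)
  }, character(1))
  for (m in Xmats) {
    if (!all(dim(m) == n)) stop("predictor dimensions must match Y")
    if (!is.null(ids) && !is.null(rownames(m)) && !identical(rownames(m), ids))
      stop("predictor id ordering must match Y")
  }

  off <- which(row(Ym) != col(Ym))        # all ordered off-diagonal dyads
  y <- Ym[off]
  X <- cbind(`(Intercept)` = 1,
             do.call(cbind, setNames(lapply(Xmats, function(m) m[off]), xnames)))
  k <- ncol(X) - 1L
  N <- length(y)

  XtX <- crossprod(X)
  cond <- kappa(XtX, exact = FALSE)
  collinear <- !is.finite(cond) || cond > 1e10
  H <- if (collinear) {
    warning("collinear predictors (condition number ", format(cond, digits = 3),
            "); using pseudo-inverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
  } else {
    solve(XtX, t(X))
  }
  beta <- drop(H %*% y)
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (N - 1) / (N - k - 1)
  f_stat <- (r2 / k) / ((1 - r2) / (N - k - 1))

  # QAP-Y null: simultaneous row/column relabeling of the response.
  # A supplied seed is used locally; the caller's RNG stream is restored.
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }
  b_obs <- abs(beta[-1])
  exceed <- setNames(numeric(k), names(b_obs))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    yp <- Ym[p, p][off]
    bp <- drop(H %*% yp)[-1]
    exceed <- exceed + (abs(bp) >= b_obs)
  }
  p_perm <- (1 + exceed) / (1 + n_perm)

  structure(list(beta = beta, adj_r2 = adj_r2, f_stat = f_stat,
                 df = c(k, N - k - 1), p_perm = p_perm,
                 n_perm = n_perm, seed = seed, n = n,
                 collinear = collinear),
            class = "mrqap_result")
}

#' @export
print.mrqap_result <- function(x, ...) {
  cat(sprintf("MRQAP on %d individuals (%d dyads): adj R^2 = %.3f, F = %.1f\n",
              x$n, x$n * (x$n - 1), x$adj_r2, x$f_stat))
  tab <- data.frame(beta = x$beta, p_perm = c(NA, x$p_perm))
  print(round(tab, 4))
  cat(sprintf("(%d QAP permutations%s)\n", x$n_perm,
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  invisible(x)
}
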