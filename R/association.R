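#' Pairwise co-occurrence counts under the gambit of the group
#'
#' Under the gambit of the group every pair of individuals identified in the
#' same daily encounter is treated as associating. This tallies, for the
#' retained individuals only, the number of daily encounters containing each
#' pair (X) and each individual (n). Masked (excluded) individuals contribute
#' nothing.
#'
#' @param records daily-consolidated, fully identified encounter data.frame.
#' @param retained_ids character vector of individuals to count.
#' @return object of class \code{pair_counts}: list with \code{ids} (sorted),
#'   \code{X} (symmetric integer matrix of joint counts, diagonal = n) and
#'   \code{n} (per-individual encounter counts).
#' @export
pair_counts <- function(records, retained_ids) {
  ids <- sort(unique(retained_ids))
  n_ids <- length(ids)
  X <- matrix(0L, n_ids, n_ids, dimnames = list(ids, ids))
  if (nrow(records) > 0L) {
    # incidence matrix: encounters x individuals, restricted to retained ids
    inc <- matrix(0L, nrow(records), n_ids)
    for (r in seq_len(nrow(records))) {
      present <- match(records$individuals[[r]], ids)
      inc[r, present[!is.na(present)]] <- 1L
    }
    X <- crossprod(inc)
    dimnames(X) <- list(ids, ids)
    storage.mode(X) <- "integer"
  }
  structure(list(ids = ids, X = X, n = setNames(diag(X), ids)),
            class = "pair_counts")
}

#' Simple-ratio association index matrix
#'
#' The simple ratio index for a pair (i, j) is
#' \deqn{SRI_{ij} = X_{ij} / (X_{ij} + Y_i + Y_j)}
#' where \eqn{X_{ij}} is the number of daily encounters containing both,
#' and \eqn{Y_i}, \eqn{Y_j} count encounters with one but not the other.
#' Since each individual appears in at most one retained encounter per day,
#' \eqn{Y_i = n_i - X_{ij}}, giving the equivalent form
#' \eqn{X_{ij} / (n_i + n_j - X_{ij})}. Values range from 0 (never
#' associated) to 1 (always associated). The diagonal is fixed to 1 for
#' clustering convenience and excluded from all statistics.
#'
#' @param counts a \code{pair_counts} object from [pair_counts()].
#' @return object of class \code{association_matrix}: list with \code{ids},
#'   \code{sri} (symmetric matrix in [0, 1], unit diagonal) and
#'   \code{counts}.
#' @export
sri_matrix <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  X <- counts$X
  n <- counts$n
  if (any(X > outer(n, n, pmin)))
    stop("data integrity error: joint count exceeds an individual count ",
         "(violates one group per individual per day)")
  denom <- outer(n, n, "+") - X
  sri <- ifelse(denom > 0, X / denom, 0)
  diag(sri) <- 1
  dimnames(sri) <- dimnames(X)
  structure(list(ids = counts$ids, sri = sri, counts = counts),
            class = "association_matrix")
}

#' Association matrix as an edge list
#'
#' @param assoc an \code{association_matrix}.
#' @param min_edge smallest index value to include (default > 0).
#' @return data.frame with columns id_i, id_j (i < j in id order), sri,
#'   x (joint count), n_i, n_j, in deterministic order.
#' @export
sri_edges <- function(assoc, min_edge = .Machine$double.eps) {
  stopifnot(inherits(assoc, "association_matrix"))
  ids <- assoc$ids
  ut <- which(upper.tri(assoc$sri), arr.ind = TRUE)
  keep <- assoc$sri[ut] >= min_edge
  ut <- ut[keep, , drop = FALSE]
  out <- data.frame(
    id_i = ids[ut[, 1]], id_j = ids[ut[, 2]],
    sri = assoc$sri[ut],
    x = assoc$counts$X[ut],
    n_i = assoc$counts$n[ut[, 1]],
    n_j = assoc$counts$n[ut[, 2]],
    stringsAsFactors = FALSE
  )
  out[order(out$id_i, out$id_j), , drop = FALSE]
}

#' Write an association matrix as wide CSV (id header row/column)
#' @param assoc an \code{association_matrix}.
#' @param path output path.
#' @export
write_association <- function(assoc, path) {
  stopifnot(inherits(assoc, "association_matrix"))
  utils::write.csv(as.data.frame(assoc$sri), path, row.names = TRUE)
  invisible(path)
}
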