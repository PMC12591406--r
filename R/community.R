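#' Average-linkage (UPGMA) clustering of an association matrix
#'
#' Agglomerates individuals on the dissimilarity d = 1 - SRI with average
#' linkage, the standard choice for association indices. Deterministic given
#' the input id ordering.
#'
#' @param assoc an \code{association_matrix}.
#' @return an object of class \code{hclust}.
#' @export
average_linkage <- function(assoc) {
  stopifnot(inherits(assoc, "association_matrix"))
  if (length(assoc$ids) < 2L) stop("need at least 2 individuals to cluster")
  d <- stats::as.dist(1 - assoc$sri)
  if (any(!is.finite(d))) stop("non-finite dissimilarities")
  stats::hclust(d, method = "average")
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the cophenetic dissimilarity (the merge
#' height at which two individuals first join a common cluster) and the
#' original dissimilarity 1 - SRI, over all unordered off-diagonal pairs.
#' Values near 1 indicate the dendrogram faithfully represents the matrix.
#'
#' @param dend \code{hclust} tree built from \code{assoc}.
#' @param assoc the \code{association_matrix} the tree was built from.
#' @return a single correlation in [-1, 1].
#' @export
cophenetic_correlation <- function(dend, assoc) {
  stopifnot(inherits(dend, "hclust"), inherits(assoc, "association_matrix"))
  coph <- stats::cophenetic(dend)
  orig <- stats::as.dist((1 - assoc$sri)[dend$labels, dend$labels])
  if (stats::sd(coph) == 0 || stats::sd(orig) == 0)
    stop("undefined cophenetic correlation: zero variance")
  stats::cor(as.vector(coph), as.vector(orig))
}

#' Weighted Newman modularity of a partition
#'
#' Modularity adapted for weighted association matrices: with edge weights
#' a_ij = SRI (off-diagonal), total weight W = sum_{i<j} a_ij and strengths
#' s_i = sum_{j != i} a_ij,
#' \deqn{Q = \sum_c \left[ w_c / W - (s_c / 2W)^2 \right]}
#' where w_c is the within-cluster weight and s_c the summed strength of
#' cluster c. Q > 0.3 conventionally indicates a meaningful division.
#'
#' @param partition cluster labels, named by individual id or aligned to
#'   \code{assoc$ids}.
#' @param assoc an \code{association_matrix}.
#' @return a single number.
#' @export
modularity_q <- function(partition, assoc) {
  stopifnot(inherits(assoc, "association_matrix"))
  ids <- assoc$ids
  if (!is.null(names(partition))) {
    if (!all(ids %in% names(partition))) stop("partition must cover all ids")
    partition <- partition[ids]
  } else if (length(partition) != length(ids)) {
    stop("partition must cover all ids")
  }
  A <- assoc$sri
  diag(A) <- 0
  W <- sum(A) / 2
  if (W == 0) stop("undefined modularity: total association weight is zero")
  s <- rowSums(A)
  q <- 0
  for (cl in unique(partition)) {
    idx <- which(partition == cl)
    w_c <- sum(A[idx, idx]) / 2
    s_c <- sum(s[idx])
    q <- q + w_c / W - (s_c / (2 * W))^2
  }
  q
}

#' Best dendrogram cut by modularity maximization
#'
#' Evaluates modularity at every distinct merge height of the dendrogram
#' (yielding partitions from k = n singletons up to one cluster) and returns
#' the partition with maximal Q. Ties are broken toward fewer clusters,
#' then toward the lower cut height. The full trace of evaluated cuts is
#' retained.
#'
#' @param dend \code{hclust} tree from [average_linkage()].
#' @param assoc the \code{association_matrix} it was built from.
#' @return object of class \code{community_result}: list with
#'   \code{partition} (named integer labels), \code{q_max}, \code{ccc}
#'   (cophenetic correlation), \code{k}, and \code{q_by_cut}
#'   (data.frame height, k, q).
#' @export
best_partition <- function(dend, assoc) {
  stopifnot(inherits(dend, "hclust"), inherits(assoc, "association_matrix"))
  n <- length(dend$labels)
  heights <- sort(unique(dend$height))
  # k = n cut (below the first merge) plus one cut at each distinct height
  cut_heights <- c(min(c(heights, 0)) - 1e-9, heights)
  cuts <- lapply(cut_heights, function(h) stats::cutree(dend, h = h))
  q <- vapply(cuts, modularity_q, numeric(1), assoc = assoc)
  k <- vapply(cuts, function(p) length(unique(p)), integer(1))
  trace <- data.frame(height = cut_heights, k = k, q = q)
  # max Q; ties -> fewer clusters, then lower height
  best <- order(-q, k, cut_heights)[1]
  ccc <- tryCatch(cophenetic_correlation(dend, assoc),
                  error = function(e) {
                    warning("cophenetic correlation undefined: ",
                            conditionMessage(e))
                    NA_real_
                  })
  structure(list(
    partition = cuts[[best]],
    q_max = q[best],
    ccc = ccc,
    k = k[best],
    q_by_cut = trace
  ), class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat("Community delineation:", x$k, "cluster(s), Q_max =",
      format(x$q_max, digits = 3), ", CCC =", format(x$ccc, digits = 3), "\n")
  print(table(x$partition))
  invisible(x)
}

#' Export the association network with cluster labels
#'
#' Writes the thresholded weighted network either as GraphML (via igraph)
#' or as a weighted edge-list CSV. Nodes carry their cluster label; edges
#' with SRI >= \code{min_edge} carry the index as weight. Output ordering is
#' deterministic (sorted ids).
#'
#' @param assoc an \code{association_matrix}.
#' @param result a \code{community_result} for the same ids.
#' @param path output file path.
#' @param min_edge minimum SRI for an edge to be written.
#' @param format "graphml" or "edgelist".
#' @return the path, invisibly.
#' @export
export_network <- function(assoc, result, path, min_edge = 0,
                           format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  edges <- sri_edges(assoc, min_edge = max(min_edge, .Machine$double.eps))
  if (format == "edgelist") {
    utils::write.csv(edges, path, row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("id_i", "id_j", "sri")],
    directed = FALSE,
    vertices = data.frame(name = assoc$ids,
                          cluster = as.integer(result$partition[assoc$ids]))
  )
  igraph::E(g)$weight <- edges$sri
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are height increments so that leaf-to-leaf path depths
#' reproduce cophenetic dissimilarities.
#'
#' @param dend \code{hclust} tree.
#' @param path output path.
#' @export
export_dendrogram <- function(dend, path) {
  stopifnot(inherits(dend, "hclust"))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the 'ape' package")
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}
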