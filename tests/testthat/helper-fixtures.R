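# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (loops, exhaustive scans) and share no code with the
# implementation paths they check.

# Build an encounter data.frame from a compact row description:
# list(list(date=, time=, ids=c(...), lon=, lat=, all_identified=), ...)
make_encounters <- function(rows) {
  df <- data.frame(
    encounter_id = vapply(seq_along(rows), function(i)
      if (!is.null(rows[[i]]$encounter_id)) rows[[i]]$encounter_id
      else sprintf("e%02d", i), character(1)),
    date = as.Date(vapply(rows, function(r) r$date, character(1))),
    time = vapply(rows, function(r) if (is.null(r$time)) NA_character_ else r$time,
                  character(1)),
    lon = vapply(rows, function(r) if (is.null(r$lon)) -125 else r$lon, numeric(1)),
    lat = vapply(rows, function(r) if (is.null(r$lat)) 47 else r$lat, numeric(1)),
    source = "small_vessel",
    stringsAsFactors = FALSE
  )
  df$individuals <- lapply(rows, function(r) sort(r$ids))
  df$group_size <- lengths(df$individuals)
  df$all_identified <- vapply(rows, function(r)
    if (is.null(r$all_identified)) TRUE else r$all_identified, logical(1))
  df$predations <- lapply(rows, function(r) r$predations)
  df
}

# Brute-force SRI recount straight from raw records: per pair, loop over
# records and apply X / (X + Yi + Yj) literally.
oracle_sri <- function(records, ids) {
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    x <- 0; yi <- 0; yj <- 0
    for (r in seq_len(nrow(records))) {
      has_i <- ids[i] %in% records$individuals[[r]]
      has_j <- ids[j] %in% records$individuals[[r]]
      if (has_i && has_j) x <- x + 1
      else if (has_i) yi <- yi + 1
      else if (has_j) yj <- yj + 1
    }
    out[i, j] <- if (x + yi + yj > 0) x / (x + yi + yj) else 0
  }
  out
}

# O(n^2) double-sum modularity oracle: Q = sum over ordered pairs in the
# same cluster of [a_ij/(2W) - s_i s_j/(2W)^2].
oracle_modularity <- function(partition, sri) {
  A <- sri
  diag(A) <- 0
  W2 <- sum(A)  # = 2W
  s <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && partition[i] == partition[j])
      q <- q + A[i, j] / W2 - s[i] * s[j] / W2^2
  }
  # add each node's own-degree term (i == j pairs belong to their cluster)
  for (i in seq_len(n)) q <- q - s[i]^2 / W2^2
  unname(q)
}

# Cophenetic dissimilarity matrix read directly off the hclust merge table,
# independent of stats::cophenetic.
oracle_cophenetic <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  cd <- matrix(0, n, n)
  for (k in seq_len(nrow(hc$merge))) {
    get_set <- function(v) if (v < 0) -v else members[[v]]
    left <- get_set(hc$merge[k, 1]); right <- get_set(hc$merge[k, 2])
    for (i in left) for (j in right) {
      cd[i, j] <- hc$height[k]; cd[j, i] <- hc$height[k]
    }
    members[[k]] <- c(left, right)
  }
  dimnames(cd) <- list(hc$labels, hc$labels)
  cd
}

# Plain multi-source Dijkstra on a land/water grid, O(V^2) linear-scan,
# 8-connectivity with sqrt(2) diagonal steps. Returns distances in meters.
oracle_dijkstra <- function(land, sources_rc, cell_size) {
  nr <- nrow(land); nc <- ncol(land)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[land] <- NA
  done[land] <- TRUE
  for (k in seq_len(nrow(sources_rc)))
    dist[sources_rc[k, 1], sources_rc[k, 2]] <- 0
  repeat {
    idx <- which(!done & is.finite(dist))
    if (length(idx) == 0) break
    u <- idx[which.min(dist[idx])]
    done[u] <- TRUE
    ur <- ((u - 1) %% nr) + 1; uc <- ((u - 1) %/% nr) + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- ur + dr; c2 <- uc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || land[r2, c2]) next
      step <- cell_size * if (dr != 0 && dc != 0) sqrt(2) else 1
      if (dist[u] + step < dist[r2, c2]) dist[r2, c2] <- dist[u] + step
    }
  }
  dist
}

# Random association matrix with a given id set (symmetric, unit diagonal).
random_assoc <- function(n, seed = 1, ids = sprintf("W%02d", seq_len(n))) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  counts <- structure(list(ids = ids,
                           X = matrix(0L, n, n, dimnames = list(ids, ids)),
                           n = stats::setNames(rep(1L, n), ids)),
                      class = "pair_counts")
  structure(list(ids = ids, sri = m, counts = counts),
            class = "association_matrix")
}

# Planted two-block association matrix: within-block SRI ~ w, between ~ b.
planted_assoc <- function(n_per_block = 20, w = 0.8, b = 0.01, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_block
  ids <- sprintf("W%02d", seq_len(n))
  block <- rep(1:2, each = n_per_block)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    base <- if (block[i] == block[j]) w else b
    v <- min(1, max(0, base + stats::runif(1, -0.05, 0.05) * base))
    m[i, j] <- v; m[j, i] <- v
  }
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  counts <- structure(list(ids = ids,
                           X = matrix(0L, n, n, dimnames = list(ids, ids)),
                           n = stats::setNames(rep(1L, n), ids)),
                      class = "pair_counts")
  list(assoc = structure(list(ids = ids, sri = m, counts = counts),
                         class = "association_matrix"),
       labels = stats::setNames(block, ids))
}

# Small test seascape: straight north-south coast on the east edge, linear
# shelf profile (km), optionally narrowing north to south.
toy_seascape <- function(nr = 40, nc = 60, cell = 1000, land_cols = 5,
                         shelf_north_km = 40, shelf_south_km = shelf_north_km,
                         slope_beyond = 25) {
  make_seascape(sim_config(
    n_rows = nr, n_cols = nc, cell_size = cell,
    land_width_km = land_cols * cell / 1000,
    shelf_km_north = shelf_north_km, shelf_km_south = shelf_south_km,
    shelf_slope_beyond = slope_beyond))
}
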