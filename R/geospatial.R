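# Per-encounter habitat covariates from an elevation grid: depth, Euclidean
# distance to shore, barrier-aware water distance to the shelf-break isobath,
# shelf width profiles, and survey-effort grids.

# Minimum Euclidean distance from each point to a set of target points,
# chunked to bound memory.
.min_dist <- function(px, py, qx, qy, chunk = 2048L) {
  n <- length(px)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1L)
    d2 <- outer(px[idx], qx, "-")^2 + outer(py[idx], qy, "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

# Snap (row, col) cells that are on land to the nearest water cell within a
# Chebyshev radius of snap_cells; errors if none is found.
.snap_to_water <- function(grid, row, col, land, snap_cells = 3L) {
  nr <- nrow(land); nc <- ncol(land)
  for (k in seq_along(row)) {
    if (!land[row[k], col[k]]) next
    found <- FALSE
    for (radius in seq_len(snap_cells)) {
      rs <- max(1, row[k] - radius):min(nr, row[k] + radius)
      cs <- max(1, col[k] - radius):min(nc, col[k] + radius)
      sub <- land[rs, cs, drop = FALSE]
      if (any(!sub)) {
        w <- which(!sub, arr.ind = TRUE)
        # nearest candidate by true cell distance
        d2 <- (rs[w[, 1]] - row[k])^2 + (cs[w[, 2]] - col[k])^2
        pick <- which.min(d2)
        row[k] <- rs[w[pick, 1]]; col[k] <- cs[w[pick, 2]]
        found <- TRUE
        break
      }
    }
    if (!found)
      stop("point on land with no water cell within ", snap_cells, " cells")
  }
  list(row = row, col = col)
}

#' Water depth at observation points
#'
#' Nearest-cell sampling of the elevation grid: depth is max(0, -elevation)
#' of the containing cell. Points falling on a land cell are snapped to the
#' nearest water cell within \code{snap_cells} cells; beyond that, an error.
#'
#' @param grid a \code{seascape_grid}.
#' @param points data.frame with planar \code{x}, \code{y} (m).
#' @param snap_cells land-snapping tolerance in cells (default 3).
#' @return numeric vector of depths (m, positive down).
#' @export
depth_at_points <- function(grid, points, snap_cells = 3L) {
  land <- classify_cells(grid)
  cell <- .point_cell(grid, points$x, points$y)
  cell <- .snap_to_water(grid, cell$row, cell$col, land, snap_cells)
  pmax(0, -grid$elevation[cbind(cell$row, cell$col)])
}

#' Euclidean distance from points to the nearest shore
#'
#' The shoreline is the set of land cells having at least one water
#' 4-neighbor; each point's distance is the straight-line distance to the
#' nearest shoreline cell center.
#'
#' @inheritParams depth_at_points
#' @return numeric vector of distances in km.
#' @export
distance_to_shore <- function(grid, points) {
  land <- classify_cells(grid)
  shore <- .shoreline_cells(land)
  sxy <- .cell_xy(grid, shore[, 1], shore[, 2])
  .min_dist(points$x, points$y, sxy$x, sxy$y) / 1000
}

# Multi-source shortest-path distance over water cells (8-connectivity,
# orthogonal step = cell_size, diagonal = cell_size * sqrt(2)), from the
# isobath source set. Returns the full field in meters (NA on land, Inf in
# water disconnected from any source).
.water_distance_field <- function(grid, land, sources_idx) {
  nr <- nrow(land); nc <- ncol(land)
  water_idx <- which(!land)                    # column-major linear indices
  node_of <- rep(NA_integer_, nr * nc)
  node_of[water_idx] <- seq_along(water_idx)
  cs <- grid$cell_size

  edges_from <- integer(0); edges_to <- integer(0); edges_w <- numeric(0)
  offs <- list(c(0L, 1L, cs), c(1L, 0L, cs),
               c(1L, 1L, cs * sqrt(2)), c(-1L, 1L, cs * sqrt(2)))
  r <- ((water_idx - 1L) %% nr) + 1L
  c_ <- ((water_idx - 1L) %/% nr) + 1L
  for (o in offs) {
    r2 <- r + o[1]; c2 <- c_ + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- !is.na(node_of[lin2])
    edges_from <- c(edges_from, node_of[water_idx[ok]][ok2])
    edges_to <- c(edges_to, node_of[lin2][ok2])
    edges_w <- c(edges_w, rep(o[3], sum(ok2)))
  }
  n_nodes <- length(water_idx)
  src_nodes <- node_of[sources_idx]
  src_nodes <- src_nodes[!is.na(src_nodes)]
  if (length(src_nodes) == 0L) stop("no isobath source cells in water")
  virtual <- n_nodes + 1L
  g <- igraph::make_empty_graph(n = virtual, directed = FALSE)
  g <- igraph::add_edges(
    g, rbind(c(edges_from, rep(virtual, length(src_nodes))),
             c(edges_to, src_nodes)),
    weight = c(edges_w, rep(0, length(src_nodes))))
  d <- igraph::distances(g, v = virtual, weights = igraph::E(g)$weight)[1, ]
  field <- matrix(NA_real_, nr, nc)
  field[water_idx] <- d[seq_len(n_nodes)]
  field
}

# Isobath source cells: water cells with depth >= level that have a water
# 4-neighbor with depth < level. Returns column-major linear indices.
.isobath_sources <- function(grid, land, level_m) {
  depth <- pmax(-grid$elevation, 0)
  depth[land] <- NA
  nr <- nrow(depth); nc <- ncol(depth)
  deep <- !land & depth >= level_m
  shallow <- !land & depth < level_m
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  adj_shallow <- shift(shallow, 1, 0) | shift(shallow, -1, 0) |
    shift(shallow, 0, 1) | shift(shallow, 0, -1)
  which(deep & adj_shallow)
}

#' Derived geospatial fields for a seascape
#'
#' Computes, once per grid, everything the point-wise covariate extractors
#' and the envelope zoning need: the land mask, per-cell depth, Euclidean
#' distance-to-shore field, and the barrier-aware water distance to the
#' \code{level_m} isobath with its signed version (negative inshore of the
#' isobath, positive offshore).
#'
#' @param grid a \code{seascape_grid}.
#' @param level_m isobath depth defining the shelf break (default 200 m).
#' @return list with \code{land}, \code{depth} (m), \code{shore_km},
#'   \code{shelf_km}, \code{signed_shelf_km} matrices and
#'   \code{isobath_cells} (linear indices).
#' @export
seascape_fields <- function(grid, level_m = 200) {
  land <- classify_cells(grid)
  depth <- pmax(-grid$elevation, 0)
  depth[land] <- NA
  shore <- .shoreline_cells(land)
  sxy <- .cell_xy(grid, shore[, 1], shore[, 2])
  water_idx <- which(!land)
  wr <- ((water_idx - 1L) %% nrow(land)) + 1L
  wc <- ((water_idx - 1L) %/% nrow(land)) + 1L
  wxy <- .cell_xy(grid, wr, wc)
  shore_km <- matrix(NA_real_, nrow(land), ncol(land))
  shore_km[water_idx] <- .min_dist(wxy$x, wxy$y, sxy$x, sxy$y) / 1000

  sources <- .isobath_sources(grid, land, level_m)
  shelf_m <- .water_distance_field(grid, land, sources)
  shelf_km <- shelf_m / 1000
  signed <- shelf_km * ifelse(depth < level_m, -1, 1)
  list(land = land, depth = depth, shore_km = shore_km,
       shelf_km = shelf_km, signed_shelf_km = signed,
       isobath_cells = sources, level_m = level_m)
}

#' Barrier-aware water distance from points to an isobath
#'
#' Distance accumulated through water cells only (8-connectivity shortest
#' path around land barriers) from each point to the nearest cell of the
#' \code{level_m} isobath. The signed version is negative where the local
#' depth is shallower than \code{level_m} (inshore of the shelf break) and
#' positive otherwise. Points in water disconnected from any isobath cell
#' get Inf with a warning.
#'
#' @inheritParams depth_at_points
#' @param level_m isobath depth in meters (default 200).
#' @param fields optional precomputed [seascape_fields()] for this grid.
#' @return data.frame with \code{dist_km} (unsigned) and \code{signed_km}.
#' @export
water_distance_to_isobath <- function(grid, points, level_m = 200,
                                      fields = NULL, snap_cells = 3L) {
  if (is.null(fields)) fields <- seascape_fields(grid, level_m)
  cell <- .point_cell(grid, points$x, points$y)
  cell <- .snap_to_water(grid, cell$row, cell$col, fields$land, snap_cells)
  idx <- cbind(cell$row, cell$col)
  d <- fields$shelf_km[idx]
  if (any(is.infinite(d)))
    warning(sum(is.infinite(d)),
            " point(s) in water disconnected from the isobath (distance Inf)")
  data.frame(dist_km = d,
             signed_km = d * ifelse(fields$depth[idx] < level_m, -1, 1))
}

# Resample a polyline (in meters) at fixed arc-length spacing, sampling at
# every multiple of `spacing` from its start (the start itself included; the
# far endpoint appears only when the length is an exact multiple). A
# zero-length line contributes its single vertex.
.resample_polyline <- function(x, y, spacing) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  L <- sum(seg)
  if (L == 0) return(data.frame(x = x[1], y = y[1]))
  s <- c(0, cumsum(seg))
  targets <- seq(0, L, by = spacing)
  data.frame(x = stats::approx(s, x, xout = targets)$y,
             y = stats::approx(s, y, xout = targets)$y)
}

#' Continental shelf width profile
#'
#' Traces the \code{level_m} isobath as contour polylines (marching squares
#' on the elevation grid), resamples each at a fixed arc-length spacing, and
#' measures each sample's Euclidean distance to the nearest shoreline cell:
#' the local width of the continental shelf.
#'
#' @param grid a \code{seascape_grid}.
#' @param level_m isobath depth (default 200 m).
#' @param spacing_m arc-length spacing between samples (default 3000 m).
#' @return data.frame with columns \code{x}, \code{y} (sample positions, m)
#'   and \code{width_km}; zero rows (with a warning) when the grid has no
#'   such isobath.
#' @export
shelf_width_profile <- function(grid, level_m = 200, spacing_m = 3000) {
  stopifnot(inherits(grid, "seascape_grid"))
  nr <- nrow(grid$elevation); nc <- ncol(grid$elevation)
  elev <- grid$elevation
  elev[is.na(elev)] <- 10  # NA treated as land, consistent with classify_cells
  xs <- grid$xll + (seq_len(nc) - 0.5) * grid$cell_size
  ys <- grid$yll + (seq_len(nr) - 0.5) * grid$cell_size
  z <- t(elev)[, nr:1, drop = FALSE]  # z[i, j] = elevation at (xs[i], ys[j])
  lines <- grDevices::contourLines(xs, ys, z, levels = -level_m)
  if (length(lines) == 0L) {
    warning("no ", level_m, " m isobath in grid; empty shelf-width profile")
    return(data.frame(x = numeric(0), y = numeric(0), width_km = numeric(0)))
  }
  land <- classify_cells(grid)
  shore <- .shoreline_cells(land)
  sxy <- .cell_xy(grid, shore[, 1], shore[, 2])
  out <- do.call(rbind, lapply(lines, function(ln)
    .resample_polyline(ln$x, ln$y, spacing_m)))
  out$width_km <- .min_dist(out$x, out$y, sxy$x, sxy$y) / 1000
  out
}

#' Survey effort grid
#'
#' Builds a relative-effort surface: survey track lines are resampled to a
#' point every \code{resample_km} of arc length, appended to the sighting
#' points, and counted within a fishnet of square cells \code{cell_km} on a
#' side.
#'
#' @param tracks data.frame with columns \code{track_id}, \code{order},
#'   \code{x}, \code{y} (planar meters); may be NULL or empty.
#' @param sighting_points data.frame with \code{x}, \code{y}; may be NULL.
#' @param cell_km fishnet cell size in km (default 5).
#' @param resample_km track resampling interval in km (default 3).
#' @param origin optional c(x0, y0) lower-left fishnet origin; defaults to
#'   the data's lower-left corner.
#' @return object of class \code{effort_grid}: list with \code{counts}
#'   (matrix, row 1 = north), \code{xll}, \code{yll}, \code{cell_size} (m)
#'   and \code{n_points}.
#' @export
effort_grid <- function(tracks, sighting_points, cell_km = 5,
                        resample_km = 3, origin = NULL) {
  pts <- list()
  if (!is.null(tracks) && nrow(tracks) > 0) {
    for (tid in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == tid, , drop = FALSE]
      tr <- tr[order(tr$order), , drop = FALSE]
      pts[[length(pts) + 1L]] <- .resample_polyline(tr$x, tr$y,
                                                    resample_km * 1000)
    }
  }
  if (!is.null(sighting_points) && nrow(sighting_points) > 0)
    pts[[length(pts) + 1L]] <- sighting_points[, c("x", "y")]
  all_pts <- do.call(rbind, pts)
  if (is.null(all_pts) || nrow(all_pts) == 0L) stop("no effort points")
  cs <- cell_km * 1000
  if (is.null(origin)) origin <- c(min(all_pts$x), min(all_pts$y))
  ci <- floor((all_pts$x - origin[1]) / cs) + 1L
  ri <- floor((all_pts$y - origin[2]) / cs) + 1L
  ncols <- max(ci); nrows <- max(ri)
  counts <- matrix(0L, nrows, ncols)
  tab <- table(factor(ri, levels = seq_len(nrows)),
               factor(ci, levels = seq_len(ncols)))
  counts <- matrix(as.integer(tab), nrows, ncols)
  counts <- counts[nrows:1, , drop = FALSE]  # row 1 = north
  structure(list(counts = counts, xll = origin[1], yll = origin[2],
                 cell_size = cs, n_points = nrow(all_pts)),
            class = "effort_grid")
}

#' Habitat covariates per identification
#'
#' Expands daily encounters to one row per identification (individual x
#' encounter) and attaches the habitat covariates at the encounter position:
#' water depth, Euclidean distance to shore, unsigned water distance to the
#' shelf-break isobath, and its signed version (negative inshore).
#'
#' @param records daily-consolidated encounter data.frame; must carry planar
#'   \code{x}, \code{y} columns (use [ll_to_planar()] for lon/lat data).
#' @param grid a \code{seascape_grid}.
#' @param level_m shelf-break isobath depth (default 200 m).
#' @param fields optional precomputed [seascape_fields()].
#' @param ids optional subset of individuals to keep (e.g., the network's
#'   retained ids).
#' @return data.frame with one row per identification: \code{encounter_id},
#'   \code{id}, \code{x}, \code{y}, \code{depth_m}, \code{dist_shore_km},
#'   \code{dist_shelf_km}, \code{signed_shelf_km}.
#' @export
encounter_covariates <- function(records, grid, level_m = 200,
                                 fields = NULL, ids = NULL) {
  stopifnot(all(c("x", "y") %in% names(records)))
  if (is.null(fields)) fields <- seascape_fields(grid, level_m)
  pts <- records[, c("x", "y")]
  depth <- depth_at_points(grid, pts)
  shore <- distance_to_shore(grid, pts)
  shelf <- water_distance_to_isobath(grid, pts, level_m, fields = fields)
  reps <- lengths(records$individuals)
  out <- data.frame(
    encounter_id = rep(records$encounter_id, reps),
    id = unlist(records$individuals),
    x = rep(records$x, reps), y = rep(records$y, reps),
    depth_m = rep(depth, reps),
    dist_shore_km = rep(shore, reps),
    dist_shelf_km = rep(shelf$dist_km, reps),
    signed_shelf_km = rep(shelf$signed_km, reps),
    stringsAsFactors = FALSE
  )
  if (!is.null(ids)) out <- out[out$id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
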