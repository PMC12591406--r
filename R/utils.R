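# Internal helpers shared across modules.

# Parse "HH:MM" or "HH:MM:SS" into minutes past midnight. NA stays NA.
.time_minutes <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", x)
  if (any(ok)) {
    parts <- strsplit(x[ok], ":", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) {
      as.numeric(p[1]) * 60 + as.numeric(p[2]) +
        if (length(p) == 3) as.numeric(p[3]) / 60 else 0
    }, numeric(1))
  }
  out
}

# Split a delimited individual-id cell into a sorted unique character vector.
.split_ids <- function(x, delim = ";") {
  lapply(strsplit(as.character(x), delim, fixed = TRUE), function(v) {
    v <- trimws(v)
    sort(unique(v[nzchar(v)]))
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to compare a recovered community partition with known ground truth.
#' 1 means identical partitions (up to label names), 0 is the expectation
#' under independent random labelings.
#'
#' @param a,b vectors of cluster labels; if named, they are aligned by name.
#' @return a single number in [-1, 1].
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0L) stop("no common names between partitions")
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b)) stop("partitions must cover the same items")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Convert lon/lat to planar coordinates (equirectangular)
#'
#' Small-region equirectangular projection about a reference point:
#' x = R cos(lat0) (lon - lon0), y = R (lat - lat0), with R = 6371 km.
#' Adequate for regional encounter data; the reverse transform is
#' [planar_to_ll()].
#'
#' @param lon,lat decimal degrees.
#' @param lon0,lat0 reference origin (degrees) mapped to (0, 0).
#' @return data.frame with columns x, y in meters.
#' @export
ll_to_planar <- function(lon, lat, lon0, lat0) {
  R <- 6371000
  data.frame(
    x = R * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180,
    y = R * (lat - lat0) * pi / 180
  )
}

#' @rdname ll_to_planar
#' @param x,y planar meters.
#' @export
planar_to_ll <- function(x, y, lon0, lat0) {
  R <- 6371000
  data.frame(
    lon = lon0 + (x / (R * cos(lat0 * pi / 180))) * 180 / pi,
    lat = lat0 + (y / R) * 180 / pi
  )
}

# Great-circle distance in meters between all pairs of points (haversine).
.haversine_matrix <- function(lon, lat) {
  rad <- pi / 180
  phi <- lat * rad
  lam <- lon * rad
  n <- length(lon)
  dphi <- outer(phi, phi, "-")
  dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + (cos(phi) %o% cos(phi)) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  6371000 * 2 * asin(sqrt(a))
}
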