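#' Seascape elevation grid
#'
#' A rectangular elevation raster in planar meters. Elevation is relative to
#' the mean-high-water datum: negative values are below water. The matrix is
#' stored with row 1 at the north edge; cells are center-registered. Cell
#' (r, c) has center x = xll + (c - 0.5) * cell_size,
#' y = yll + (nrow - r + 0.5) * cell_size, where (xll, yll) is the lower-left
#' corner of the grid (ESRI ASCII convention).
#'
#' @param elevation numeric matrix of elevations (m), row 1 = north.
#' @param cell_size cell edge length in meters (> 0).
#' @param xll,yll planar coordinates of the grid's lower-left corner (m).
#' @param crs free-text projection tag (default "planar").
#' @return object of class \code{seascape_grid}.
#' @export
seascape_grid <- function(elevation, cell_size, xll = 0, yll = 0,
                          crs = "planar") {
  stopifnot(is.matrix(elevation), is.numeric(elevation), cell_size > 0)
  structure(list(elevation = elevation, cell_size = cell_size,
                 xll = xll, yll = yll, crs = crs),
            class = "seascape_grid")
}

#' @export
print.seascape_grid <- function(x, ...) {
  cat(sprintf("seascape_grid: %d x %d cells @ %g m (%s)\n",
              nrow(x$elevation), ncol(x$elevation), x$cell_size, x$crs))
  cat(sprintf("  elevation range: %.1f to %.1f m\n",
              min(x$elevation, na.rm = TRUE), max(x$elevation, na.rm = TRUE)))
  invisible(x)
}

# Cell centers for given row/col vectors.
.cell_xy <- function(grid, row, col) {
  list(x = grid$xll + (col - 0.5) * grid$cell_size,
       y = grid$yll + (nrow(grid$elevation) - row + 0.5) * grid$cell_size)
}

# Containing cell for planar points; errors if any point is out of bounds.
.point_cell <- function(grid, x, y) {
  nr <- nrow(grid$elevation); nc <- ncol(grid$elevation)
  col <- floor((x - grid$xll) / grid$cell_size) + 1L
  row <- nr - floor((y - grid$yll) / grid$cell_size)
  # points exactly on the top/right edge belong to the last cell
  col[x == grid$xll + nc * grid$cell_size] <- nc
  row[y == grid$yll + nr * grid$cell_size] <- 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr | is.na(col) | is.na(row)
  if (any(bad))
    stop("point(s) outside grid bounds: index ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  list(row = as.integer(row), col = as.integer(col))
}

#' Classify grid cells as land or water
#'
#' A cell is land when its elevation is at least 1 m above the mean-high-
#' water datum, water otherwise. The threshold value 1 m is itself land.
#' NA elevations are treated as land by default (with a warning).
#'
#' @param grid a \code{seascape_grid}.
#' @param na_as_land treat NA cells as land (default TRUE).
#' @return logical matrix, TRUE = land.
#' @export
classify_cells <- function(grid, na_as_land = TRUE) {
  stopifnot(inherits(grid, "seascape_grid"))
  elev <- grid$elevation
  land <- elev >= 1
  if (anyNA(land)) {
    warning(sum(is.na(land)), " NA elevation cells treated as ",
            if (na_as_land) "land" else "water")
    land[is.na(land)] <- na_as_land
  }
  land
}

# Land cells with at least one water 4-neighbor (the shoreline).
.shoreline_cells <- function(land) {
  nr <- nrow(land); nc <- ncol(land)
  if (!any(land)) stop("no land in grid: cannot derive a shoreline")
  if (all(land)) stop("no water in grid")
  water <- !land
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- water[rs - dr, cs - dc]
    out
  }
  touch_water <- pad(water, 1, 0) | pad(water, -1, 0) |
    pad(water, 0, 1) | pad(water, 0, -1)
  which(land & touch_water, arr.ind = TRUE)
}

#' Read an ESRI ASCII grid
#'
#' @param path path to an .asc file (header: ncols, nrows, xllcorner,
#'   yllcorner, cellsize, optional NODATA_value).
#' @param crs projection tag to attach.
#' @return a \code{seascape_grid}.
#' @export
read_esri_ascii <- function(path, crs = "planar") {
  lines <- readLines(path, n = 6)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))) &&
        grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else break
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[key]])) stop("ESRI ASCII header missing ", key)
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ESRI ASCII grid: expected ", hdr$ncols * hdr$nrows,
         " values, found ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  seascape_grid(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, crs = crs)
}

#' Write a grid (or zone matrix) as ESRI ASCII
#'
#' @param grid a \code{seascape_grid}, or a plain matrix plus geometry
#'   arguments matching [seascape_grid()].
#' @param path output path.
#' @param nodata value standing in for NA (default -9999).
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "seascape_grid"))
  m <- grid$elevation
  m[is.na(m)] <- nodata
  hdr <- sprintf(
    "ncols %d\nnrows %d\nxllcorner %.6f\nyllcorner %.6f\ncellsize %.6f\nNODATA_value %g",
    ncol(m), nrow(m), grid$xll, grid$yll, grid$cell_size, nodata)
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
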