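test_that("land/water classification follows the 1 m elevation rule", {
  g <- seascape_grid(matrix(c(5, -30, 1, 0.99, -0.5, 2), 2, 3), 100)
  land <- classify_cells(g)
  expect_identical(land, matrix(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE), 2, 3))

  # checkerboard equals the elementwise threshold oracle
  set.seed(1)
  m <- matrix(stats::runif(100, -50, 50), 10, 10)
  expect_identical(classify_cells(seascape_grid(m, 90)), m >= 1)

  # NA cells default to land with a warning
  m[1, 1] <- NA
  expect_warning(landNA <- classify_cells(seascape_grid(m, 90)), "NA")
  expect_true(landNA[1, 1])

  # all-water grid errors cleanly downstream at shoreline extraction
  allw <- seascape_grid(matrix(-10, 4, 4), 100)
  expect_error(distance_to_shore(allw, data.frame(x = 50, y = 50)), "no land")
})

test_that("depth sampling flips sign, snaps off land, and checks bounds", {
  elev <- matrix(c(-77.2, -10, 5, -20), 2, 2)  # col 2 row 1 = 5 (land)
  g <- seascape_grid(elev, 100)
  expect_equal(depth_at_points(g, data.frame(x = 50, y = 150)), 77.2)
  # point over the land cell snaps to a water neighbor within 3 cells
  d <- depth_at_points(g, data.frame(x = 150, y = 150))
  expect_true(d %in% c(77.2, 10, 20))
  expect_error(depth_at_points(g, data.frame(x = 200.01, y = 50)),
               "outside grid bounds")
  # land point with no water within tolerance errors
  gl <- seascape_grid(matrix(c(rep(5, 99), -10), 10, 10), 100)
  expect_error(depth_at_points(gl, data.frame(x = 50, y = 950), snap_cells = 2),
               "no water cell")
})

test_that("distance to shore matches straight-line geometry and brute force", {
  # straight coast: land in the last 2 columns, water elsewhere
  elev <- matrix(-50, 20, 30)
  elev[, 29:30] <- 5
  g <- seascape_grid(elev, 100)
  # point 10 cells (1000 m) due west of the shoreline cell centers
  pt <- data.frame(x = 28.5 * 100 - 1000, y = 10.5 * 100)
  expect_equal(distance_to_shore(g, pt), 1.0)
  # point on a shoreline-adjacent water cell center: half a cell away
  pt2 <- data.frame(x = 27.5 * 100, y = 10.5 * 100)
  expect_equal(distance_to_shore(g, pt2), 0.1)

  # convex bay: equals exhaustive min over all shoreline cells
  set.seed(5)
  bay <- matrix(-30, 25, 25)
  for (r in 1:25) {
    start <- min(25, max(1, 20 - round(6 * sin(r / 4))))
    bay[r, start:25] <- 5
  }
  gb <- seascape_grid(bay, 100)
  land <- classify_cells(gb)
  pts <- data.frame(x = stats::runif(20, 100, 1200),
                    y = stats::runif(20, 100, 2400))
  got <- distance_to_shore(gb, pts)
  # oracle: scan every land cell with a water 4-neighbor
  shore <- list()
  for (r in 1:25) for (cc in 1:25) {
    if (!land[r, cc]) next
    nb <- rbind(c(r - 1, cc), c(r + 1, cc), c(r, cc - 1), c(r, cc + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 25 & nb[, 2] >= 1 & nb[, 2] <= 25, , drop = FALSE]
    if (any(!land[nb])) shore[[length(shore) + 1]] <- c(r, cc)
  }
  shore <- do.call(rbind, shore)
  sx <- (shore[, 2] - 0.5) * 100
  sy <- (25 - shore[, 1] + 0.5) * 100
  want <- sapply(seq_len(nrow(pts)), function(i)
    min(sqrt((pts$x[i] - sx)^2 + (pts$y[i] - sy)^2))) / 1000
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("water distance to the isobath follows grid geometry", {
  # straight shelf: isobath along a known column, no barriers
  g <- toy_seascape(nr = 30, nc = 60, cell = 90, land_cols = 5,
                    shelf_north_km = 2, shelf_south_km = 2)
  flds <- seascape_fields(g)
  src <- which(!is.na(flds$shelf_km) & flds$shelf_km == 0, arr.ind = TRUE)
  expect_gt(nrow(src), 0)
  # a point exactly on a source cell center: 0 km
  r1 <- src[1, 1]; c1 <- src[1, 2]
  pt0 <- data.frame(x = (c1 - 0.5) * 90, y = (30 - r1 + 0.5) * 90)
  d0 <- water_distance_to_isobath(g, pt0, fields = flds)
  expect_equal(d0$dist_km, 0)
  # 20 cells orthogonally along the same row: 20 * 90 m = 1.8 km
  pt20 <- data.frame(x = (c1 - 20 - 0.5) * 90, y = (30 - r1 + 0.5) * 90)
  d20 <- water_distance_to_isobath(g, pt20, fields = flds)
  expect_equal(d20$dist_km, 1.8)
  # sign: shallow side negative, deep side positive
  expect_lt(water_distance_to_isobath(
    g, data.frame(x = (c1 + 5 - 0.5) * 90, y = pt0$y), fields = flds)$signed_km, 0)
  expect_gt(water_distance_to_isobath(
    g, data.frame(x = (c1 - 10 - 0.5) * 90, y = pt0$y), fields = flds)$signed_km, 0)
})

test_that("barrier detours match an independent Dijkstra oracle", {
  # shallow band in the north (the isobath runs along its southern edge);
  # a land arm attached to the eastern mainland blocks the direct route
  # north from the pocket south of it
  elev <- matrix(-300, 40, 40)
  elev[1:5, ] <- -100                # shallow band: isobath source boundary
  elev[, 38:40] <- 5                 # mainland on the east
  elev[18:22, 10:40] <- 5            # arm jutting west from the mainland
  g <- seascape_grid(elev, 100)
  land <- classify_cells(g)
  flds <- seascape_fields(g, level_m = 200)
  src_rc <- arrayInd(flds$isobath_cells, c(40L, 40L))
  oracle <- oracle_dijkstra(land, src_rc, 100)
  expect_equal(flds$shelf_km[!land], oracle[!land] / 1000, tolerance = 1e-9)

  # a point south of the arm must detour around its western tip: strictly
  # farther than its straight-line distance to the nearest source
  behind <- data.frame(x = 30.5 * 100, y = (40 - 30 + 0.5) * 100)
  sxy <- list(x = (src_rc[, 2] - 0.5) * 100, y = (40 - src_rc[, 1] + 0.5) * 100)
  straight <- min(sqrt((behind$x - sxy$x)^2 + (behind$y - sxy$y)^2)) / 1000
  dd <- water_distance_to_isobath(g, behind, fields = flds)
  expect_gt(dd$dist_km, straight)

  # water distance >= Euclidean everywhere (grid metric dominates)
  wi <- which(!land & is.finite(flds$shelf_km))
  eu <- matrix(NA_real_, 40, 40)
  wr <- ((wi - 1) %% 40) + 1; wc <- ((wi - 1) %/% 40) + 1
  px <- (wc - 0.5) * 100; py <- (40 - wr + 0.5) * 100
  eu_d <- sapply(seq_along(wi), function(k)
    min(sqrt((px[k] - sxy$x)^2 + (py[k] - sxy$y)^2))) / 1000
  expect_true(all(flds$shelf_km[wi] >= eu_d - 1e-9))
})

test_that("disconnected water bodies get an infinite-distance flag", {
  elev <- matrix(-300, 10, 10)
  elev[, 1] <- -100                   # shallow edge: isobath exists in the west
  elev[, 5] <- 5                      # wall splits the grid
  elev[, 6:10] <- -50                 # east half too shallow for a 200 m isobath
  g <- seascape_grid(elev, 100)
  flds <- seascape_fields(g, level_m = 200)
  expect_warning(
    d <- water_distance_to_isobath(g, data.frame(x = 750, y = 500), fields = flds),
    "disconnected")
  expect_true(is.infinite(d$dist_km))
})

test_that("shelf width profile recovers constructed geometries", {
  # constant 40 km shelf: all widths 40 km within a cell
  g <- toy_seascape(nr = 40, nc = 70, cell = 1000, land_cols = 5,
                    shelf_north_km = 40, shelf_south_km = 40)
  prof <- shelf_width_profile(g, spacing_m = 3000)
  expect_gt(nrow(prof), 5)
  expect_true(all(abs(prof$width_km - 40) < 1))

  # linear 50 -> 12 km narrowing: widths monotone along the contour
  g2 <- toy_seascape(nr = 80, nc = 80, cell = 1000, land_cols = 5,
                     shelf_north_km = 50, shelf_south_km = 12)
  prof2 <- shelf_width_profile(g2, spacing_m = 3000)
  w <- prof2$width_km[order(prof2$y, decreasing = TRUE)]   # north to south
  expect_true(all(diff(w) <= 1))   # monotone within one cell tolerance
  expect_true(max(w) > 45 && min(w) < 15)

  # spacing larger than the contour length -> a single sample per line
  g3 <- toy_seascape(nr = 5, nc = 60, cell = 1000, land_cols = 5,
                     shelf_north_km = 30, shelf_south_km = 30)
  prof3 <- shelf_width_profile(g3, spacing_m = 1e6)
  expect_equal(nrow(prof3), 1)

  # no isobath at all -> empty profile with a warning
  shallow <- seascape_grid(cbind(matrix(-50, 10, 9), matrix(5, 10, 1)), 1000)
  expect_warning(p0 <- shelf_width_profile(shallow), "no 200 m isobath")
  expect_equal(nrow(p0), 0)
})

test_that("effort grid resamples tracks and conserves counts", {
  # 30 km straight track at 3 km spacing: points at 0, 3, ..., 30 -> 11
  tr <- data.frame(track_id = "t1", order = 1:2, x = c(0, 30000), y = 0)
  eg <- effort_grid(tr, NULL, cell_km = 5, resample_km = 3)
  expect_equal(eg$n_points, 11)
  expect_equal(sum(eg$counts), 11)

  # 10 sightings in one cell, none elsewhere
  pts <- data.frame(x = rep(2500, 10), y = rep(2500, 10))
  eg2 <- effort_grid(NULL, pts, cell_km = 5)
  expect_equal(sum(eg2$counts == 10), 1)
  expect_equal(sum(eg2$counts), 10)

  # shifting the fishnet origin changes cells but conserves the total
  tr2 <- data.frame(track_id = "t1", order = 1:3,
                    x = c(0, 12000, 24000), y = c(0, 8000, 0))
  pts2 <- data.frame(x = stats::runif(25, 0, 20000), y = stats::runif(25, 0, 9000))
  e_a <- effort_grid(tr2, pts2, cell_km = 5, origin = c(0, 0))
  e_b <- effort_grid(tr2, pts2, cell_km = 5, origin = c(-2500, -2500))
  expect_equal(sum(e_a$counts), sum(e_b$counts))
  expect_equal(e_a$n_points, e_b$n_points)

  # degenerate zero-length track contributes its single vertex
  tr0 <- data.frame(track_id = "z", order = 1:2, x = c(5, 5), y = c(7, 7))
  expect_equal(effort_grid(tr0, NULL)$n_points, 1)
})

test_that("ESRI ASCII grids round-trip including NODATA", {
  m <- matrix(stats::rnorm(30), 5, 6)
  m[2, 3] <- NA
  g <- seascape_grid(m, 250, xll = 1000, yll = 2000)
  f <- tempfile(fileext = ".asc")
  write_esri_ascii(g, f)
  g2 <- read_esri_ascii(f)
  expect_equal(g2$elevation, g$elevation, tolerance = 1e-6)
  expect_equal(g2$cell_size, 250)
  expect_equal(g2$xll, 1000)
  expect_equal(g2$yll, 2000)
})

test_that("covariate extraction yields one row per identification", {
  g <- toy_seascape(nr = 20, nc = 40, cell = 1000, land_cols = 4,
                    shelf_north_km = 15, shelf_south_km = 15)
  rec <- make_encounters(list(
    list(date = "2020-01-01", ids = c("A", "B")),
    list(date = "2020-01-02", ids = c("A", "B", "C"))
  ))
  rec$x <- c(30000, 10000)   # nearshore and offshore points
  rec$y <- c(10000, 10000)
  cov <- encounter_covariates(rec, g)
  expect_equal(nrow(cov), 5)
  expect_equal(sort(unique(cov$id)), c("A", "B", "C"))
  expect_true(all(cov$depth_m >= 0))
  expect_true(all(cov$dist_shore_km >= 0))
  # signed distance is negative inshore (depth < 200 m there)
  expect_lt(cov$signed_shelf_km[1], 0)
})
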