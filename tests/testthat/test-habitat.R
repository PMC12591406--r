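toy_cov <- function(values_by_id) {
  # one identification per value, ids repeated as needed
  do.call(rbind, lapply(names(values_by_id), function(id) {
    v <- values_by_id[[id]]
    data.frame(encounter_id = sprintf("%s_e%d", id, seq_along(v)), id = id,
               x = 0, y = 0, depth_m = v, dist_shore_km = v,
               dist_shelf_km = v, signed_shelf_km = -v,
               stringsAsFactors = FALSE)
  }))
}

test_that("habitat summaries report mean, SE, range, and n per cluster", {
  cov <- toy_cov(list(a = c(1, 2, 3), b = 7))
  part <- c(a = "inner", b = "outer")
  s <- habitat_summary(cov, part, "dist_shore_km")
  inner <- s[s$cluster == "inner", ]
  expect_equal(inner$mean, 2)
  expect_equal(inner$se, 1 / sqrt(3), tolerance = 1e-10)  # sd = 1
  expect_equal(c(inner$min, inner$max, inner$n), c(1, 3, 3))
  outer <- s[s$cluster == "outer", ]
  expect_equal(outer$se, 0)       # single identification: SE flagged undefined
  expect_false(outer$se_defined)

  # identical clusters of data give identical summaries
  cov2 <- toy_cov(list(a = c(2, 4, 9), b = c(2, 4, 9)))
  s2 <- habitat_summary(cov2, c(a = "x", b = "y"), "depth_m")
  expect_equal(s2$mean[1], s2$mean[2])
  expect_equal(s2$se[1], s2$se[2])

  expect_warning(
    habitat_summary(cov, c(a = "inner", b = "outer", zz = "ghost"), "depth_m"),
    "empty cluster")
})

test_that("rank-sum test matches exhaustive enumeration on small samples", {
  # x = {1,2}, y = {10,11}: U = 0, exact two-sided p = 2/6
  r <- rank_sum_test(c(1, 2), c(10, 11))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  expect_equal(r$method, "exact")

  # same multiset -> p = 1
  expect_equal(rank_sum_test(c(3, 5, 5), c(3, 5, 5))$p, 1)
  # all values identical across both samples -> degenerate p = 1
  expect_equal(rank_sum_test(rep(4, 3), rep(4, 5))$p, 1)

  # exact branch equals a full enumeration oracle for all |x|+|y| <= 8
  set.seed(31)
  for (i in 1:20) {
    m <- sample(1:4, 1); n <- sample(1:4, 1)
    x <- sample(1:5, m, replace = TRUE)   # ties likely
    y <- sample(1:5, n, replace = TRUE)
    got <- rank_sum_test(x, y)
    r_all <- rank(c(x, y))
    combos <- utils::combn(m + n, m)
    Us <- colSums(matrix(r_all[combos], nrow = m)) - m * (m + 1) / 2
    mu <- m * n / 2
    p_oracle <- mean(abs(Us - mu) >= abs(got$U - mu) - 1e-12)
    expect_equal(got$p, p_oracle)
  }
})

test_that("rank-sum normal branch is sane and near wilcox.test", {
  set.seed(77)
  x <- stats::rnorm(200)
  y <- stats::rnorm(200) + 1
  r <- rank_sum_test(x, y)
  expect_equal(r$method, "normal")
  expect_lt(r$p, 0.001)
  w <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(unname(r$U), unname(w$statistic))
  expect_equal(r$p, w$p.value, tolerance = 1e-9)

  # with heavy ties the tie-corrected variance still tracks wilcox.test
  x2 <- sample(1:4, 60, replace = TRUE)
  y2 <- sample(2:5, 60, replace = TRUE)
  r2 <- rank_sum_test(x2, y2)
  w2 <- stats::wilcox.test(x2, y2, correct = TRUE, exact = FALSE)
  expect_equal(r2$p, w2$p.value, tolerance = 1e-9)
})

test_that("envelope thresholds follow the interpolated quantile rule", {
  cov <- toy_cov(list(a = 1:10, b = 1:10))
  part <- c(a = "inner", b = "outer")
  env <- fit_envelope(cov, part, inner = "inner", outer = "outer", q = 0.9)
  expect_equal(env$inner_shore_threshold_km, 9.1)   # linear interpolation
  expect_equal(env$outer_shelf_threshold_km, 9.1)   # |signed| = same values
  expect_gte(env$coverage_inner, 0.9)
  expect_lte(env$coverage_inner, 0.9 + 1 / env$n_inner)

  # constant data: threshold equals the constant for any q
  cov2 <- toy_cov(list(a = rep(7, 5), b = rep(3, 4)))
  env2 <- fit_envelope(cov2, part, "inner", "outer", q = 0.5)
  expect_equal(env2$inner_shore_threshold_km, 7)
  expect_equal(env2$outer_shelf_threshold_km, 3)

  expect_error(fit_envelope(cov, part, "inner", "outer", q = 1.2), "q must be")

  # coverage property on continuous data: within 1/n of q on either side,
  # and exactly floor((n-1)q + 1)/n for distinct values
  set.seed(4)
  cov3 <- toy_cov(list(a = stats::rlnorm(200), b = stats::rlnorm(150)))
  for (q in c(0.5, 0.9, 0.95)) {
    e <- fit_envelope(cov3, part, "inner", "outer", q = q)
    expect_equal(e$coverage_inner, floor((e$n_inner - 1) * q + 1) / e$n_inner)
    expect_equal(e$coverage_outer, floor((e$n_outer - 1) * q + 1) / e$n_outer)
    expect_lte(abs(e$coverage_inner - q), 1 / e$n_inner)
    expect_lte(abs(e$coverage_outer - q), 1 / e$n_outer)
  }
})

test_that("envelope zones appear only where the shelf comes close to shore", {
  env <- structure(list(inner_shore_threshold_km = 5,
                        outer_shelf_threshold_km = 10, q = 0.9),
                   class = "envelope_model")
  # wide shelf (40 km): inner and outer bands cannot meet
  wide <- toy_seascape(nr = 30, nc = 70, cell = 1000, land_cols = 5,
                       shelf_north_km = 40, shelf_south_km = 40)
  zw <- envelope_zones(wide, env)
  expect_equal(sum(zw == 3, na.rm = TRUE), 0)
  expect_gt(sum(zw == 1, na.rm = TRUE), 0)
  expect_gt(sum(zw == 2, na.rm = TRUE), 0)

  # narrow shelf (3 km): an overlap band must exist
  narrow <- toy_seascape(nr = 30, nc = 70, cell = 1000, land_cols = 5,
                         shelf_north_km = 3, shelf_south_km = 3)
  zn <- envelope_zones(narrow, env)
  expect_gt(sum(zn == 3, na.rm = TRUE), 0)

  # land cells are never labeled
  land <- classify_cells(wide)
  expect_true(all(is.na(zw[land])))
  expect_true(all(!is.na(zw[!land])))
})

test_that("mixed associations are counted per encounter", {
  part <- c(A = "inner", B = "outer", C = "inner", D = "inner")
  rec <- make_encounters(list(
    list(date = "2020-01-01", ids = c("A", "B")),          # mixed
    list(date = "2020-01-02", ids = c("A", "C")),
    list(date = "2020-01-03", ids = c("B")),
    list(date = "2020-01-04", ids = c("A", "C", "D")),
    list(date = "2020-01-05", ids = c("C", "B")),          # mixed
    list(date = "2020-01-06", ids = c("D")),
    list(date = "2020-01-07", ids = c("A")),
    list(date = "2020-01-08", ids = c("C")),
    list(date = "2020-01-09", ids = c("A", "D")),
    list(date = "2020-01-10", ids = c("D", "C"))
  ))
  mx <- mixed_associations(rec, part)
  expect_equal(mx$count, 2)
  expect_equal(mx$proportion, 0.2)
  expect_equal(sum(mx$roster$mixed), 2)
  # mixed + pure-inner + pure-outer = total
  pure <- nrow(rec) - mx$count
  expect_equal(mx$count + pure, nrow(rec))

  # no outer individuals present -> zero mixed
  mx0 <- mixed_associations(rec[c(2, 4), ], c(A = "inner", C = "inner", D = "inner"))
  expect_equal(mx0$count, 0)
})

test_that("prey composition percentages sum to 100 within clusters", {
  part <- c(A = "inner", B = "outer")
  rec <- make_encounters(list(
    list(date = "2020-01-01", ids = "A",
         predations = data.frame(prey_species = "harbor_seal", count = 64L)),
    list(date = "2020-01-02", ids = "A",
         predations = data.frame(prey_species = "harbor_porpoise", count = 36L)),
    list(date = "2020-01-03", ids = "B",
         predations = data.frame(prey_species = "california_sea_lion", count = 1L))
  ))
  tab <- prey_composition(rec, part)
  inner <- tab[tab$cluster == "inner", ]
  expect_equal(inner$percent[inner$prey_species == "harbor_seal"], 64)
  expect_equal(sum(inner$percent), 100)
  outer <- tab[tab$cluster == "outer", ]
  expect_equal(outer$percent, 100)  # single event -> 100% one species

  expect_warning(
    empty <- prey_composition(make_encounters(list(
      list(date = "2020-01-01", ids = "A"))), part),
    "no predation")
  expect_equal(nrow(empty), 0)
})

test_that("simulated prey mixtures are recovered within multinomial error", {
  cfg <- sim_config(n_days = 150, pred_rate = 0.5)
  ses <- make_seascape(cfg)
  pop <- simulate_population(cfg, seed = 5)
  sim <- simulate_encounters(pop$registry, pop$truth, ses, cfg, seed = 6)
  tab <- prey_composition(sim$encounters, pop$truth$subpop)
  hs <- tab$percent[tab$cluster == "inner" & tab$prey_species == "harbor_seal"]
  n_inner <- sum(tab$events[tab$cluster == "inner"])
  moe <- 100 * 3 * sqrt(0.64 * 0.36 / n_inner)
  expect_gt(n_inner, 100)
  expect_lt(abs(hs - 64), moe)
})
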