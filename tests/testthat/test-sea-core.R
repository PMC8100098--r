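test_that("raw_score matches worked examples and the brute-force oracle", {
  # singleton pair at Tc 0.8: 9 bits each, 8 shared
  a <- fp_set(afp(0:8))
  b <- fp_set(afp(c(0:7, 20)))
  expect_equal(tanimoto_matrix(a, b)[1, 1], 0.8)
  expect_equal(raw_score(a, b, 0.57), 0.8)
  # below threshold: empty sum
  expect_equal(raw_score(a, b, 0.9), 0)
  # random 5 x 7 sets vs explicit double loop
  for (seed in 1:5) {
    A <- random_fp_set(5, len = 128, n_on = 20, seed = seed)
    B <- random_fp_set(7, len = 128, n_on = 20, seed = seed + 100)
    expect_identical(raw_score(A, B, 0.3), raw_score_oracle(A, B, 0.3))
  }
  expect_error(raw_score(a, random_fp_set(2, len = 999)), "length mismatch")
})

test_that("zscore centers and scales by the fitted null", {
  w <- tiny_world()
  model <- calibrate_tiny(w$reference, seed = 5)
  mu <- seavote:::bg_mu(model, 25)
  sig <- seavote:::bg_sigma(model, 25)
  expect_equal(zscore(mu, 25, model), 0)
  expect_equal(zscore(mu + sig, 25, model), 1)
  expect_equal(zscore(mu - 2 * sig, 25, model), -2)
  expect_error(zscore(1, model$max_n * 11, model), "beyond")
})

test_that("evd_pvalue matches extended-precision evaluation to 12 digits", {
  # frozen oracle: 1 - exp(-exp(-z*pi/sqrt(6) - gamma)) at 50-digit precision
  oracle <- c(`-2` = 0.99932450879822359, `-1` = 0.86794319356500036,
              `0` = 0.42962399832546785, `0.5` = 0.25597164233637572,
              `1` = 0.14419192604508447, `2` = 0.042263604427105795,
              `3` = 0.011904401270548301, `5` = 0.00092065487561129996,
              `8` = 1.9646248981460943e-5, `10` = 1.5110364950741849e-6,
              `15` = 2.4788697699638845e-9, `20` = 4.0666064183000354e-12)
  z <- as.numeric(names(oracle))
  expect_equal(evd_pvalue(z), unname(oracle), tolerance = 1e-12)
  # limits and monotonicity
  expect_equal(evd_pvalue(-50), 1)
  expect_lt(evd_pvalue(80), 1e-43)
  grid <- evd_pvalue(seq(-10, 20, by = 0.05))
  expect_true(all(diff(grid) <= 0))
  # strictly decreasing wherever the tail has not saturated at 1 in double
  # precision
  live <- grid < 1
  expect_true(all(diff(grid[live]) < 0))
  expect_error(evd_pvalue(Inf), "finite")
})

test_that("background calibration is seed-reproducible and non-degenerate", {
  w <- tiny_world()
  m1 <- calibrate_tiny(w$reference, seed = 77)
  m2 <- calibrate_tiny(w$reference, seed = 77)
  expect_identical(m1[c("mu_slope", "mu_intercept", "sigma_slope",
                        "sigma_intercept")],
                   m2[c("mu_slope", "mu_intercept", "sigma_slope",
                        "sigma_intercept")])
  m3 <- calibrate_tiny(w$reference, seed = 78)
  expect_false(identical(m1$mu_slope, m3$mu_slope))
  expect_true(all(seavote:::bg_sigma(m1, m1$cell_stats$n) > 0))
})

test_that("degenerate pools abort calibration with instructions", {
  # identical fingerprints: every raw score is exactly n, zero spread
  same <- fp_set(lapply(1:30, function(i) afp(0:9, len = 64)),
                 ids = sprintf("l%d", 1:30))
  ref <- sea_reference(list(T1 = seavote:::fp_subset(same, 1:15),
                            T2 = seavote:::fp_subset(same, 16:30)))
  expect_error(calibrate_background(ref, seed = 1, size_grid = tiny_grid),
               "degenerate")
  # threshold no pair can cross: all-zero scores
  w <- tiny_world()
  expect_error(calibrate_background(w$reference, tc_threshold = 0.999, seed = 1,
                                    size_grid = tiny_grid),
               "lower tc_threshold")
  # and a pool smaller than the largest grid cell is refused outright
  expect_error(calibrate_background(w$reference, seed = 1), "too small")
})

test_that("background model JSON round-trips", {
  w <- tiny_world()
  m <- calibrate_tiny(w$reference, seed = 9)
  path <- tempfile(fileext = ".json")
  write_background(m, path)
  m2 <- read_background(path)
  expect_equal(m2$mu_slope, m$mu_slope)
  expect_equal(m2$sigma_intercept, m$sigma_intercept)
  expect_equal(m2$cell_stats$mean, m$cell_stats$mean)
  expect_identical(m2$calib_seed, m$calib_seed)
  expect_equal(zscore(3, 25, m2), zscore(3, 25, m))
})

test_that("search ranks the planted target first and is order-invariant", {
  w <- tiny_world()
  model <- calibrate_tiny(w$reference, seed = 5)
  for (cid in names(w$queries)) {
    hits <- sea_search(w$queries[[cid]], w$reference, model, compound_id = cid)
    expect_equal(nrow(hits), 4L)  # one hit per reference target
    truth <- w$truth$target_id[w$truth$compound_id == cid]
    expect_identical(hits$target_id[1], truth)
    expect_equal(hits$e_value, hits$p_value * 4)
    expect_true(!is.unsorted(hits$e_value))
  }
  # permuting the reference targets must not change the output
  perm <- sea_reference(w$reference$sets[c(3, 1, 4, 2)])
  h1 <- sea_search(w$queries[[1]], w$reference, model)
  h2 <- sea_search(w$queries[[1]], perm, model)
  expect_identical(h1, h2)
})

test_that("a query with no shared bits scores zero everywhere", {
  w <- tiny_world()
  model <- calibrate_tiny(w$reference, seed = 5)
  # bits far outside every allocated region
  q <- fp_set(afp(480:505, len = 512), ids = "offworld")
  hits <- sea_search(q, w$reference, model)
  expect_true(all(hits$raw_score == 0))
  expect_equal(length(unique(hits$p_value)), 1L)  # same null at equal n
  expect_equal(hits$max_tc, rep(0, 4))
})

test_that("reference TSV serialization round-trips", {
  w <- tiny_world()
  path <- tempfile(fileext = ".tsv")
  write_reference(w$reference, path)
  ref2 <- read_reference(path)
  expect_identical(ref2$target_ids, w$reference$target_ids)
  expect_equal(as.matrix(ref2$pool$mat), as.matrix(w$reference$pool$mat),
               ignore_attr = TRUE)
})
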