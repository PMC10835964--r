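test_that("response transforms invert exactly and validate positivity", {
  y <- c(1, exp(1), exp(2))
  expect_equal(transform_response(y, "natural_log"), c(0, 1, 2))
  expect_equal(transform_response(y, "identity"), y)
  set.seed(20)
  z <- runif(50, 0.1, 10)
  expect_equal(back_transform(transform_response(z, "natural_log"),
                              "natural_log"), z, tolerance = 1e-12)
  expect_error(transform_response(c(1, -2, 3), "natural_log"), "2")
})

test_that("region draws respect count, bounds, and determinism", {
  g <- spectral_grid()
  set.seed(30)
  for (i in 1:50) {
    r <- sample_region_set(g)
    r <- unclass(r)
    expect_gte(nrow(r), 1); expect_lte(nrow(r), 8)
    expect_true(all(r[, 1] >= 350 & r[, 2] <= 2500))
    expect_true(all(r[, 2] - r[, 1] >= 20))
  }
  set.seed(31); a <- sample_region_set(g)
  set.seed(31); b <- sample_region_set(g)
  expect_identical(a, b)
  # count distribution covers every value 1..8
  set.seed(32)
  counts <- replicate(2000, nrow(unclass(sample_region_set(g))))
  expect_true(all(1:8 %in% counts))
  expect_error(sample_region_set(g, max_regions = 0), "max_regions")
  expect_error(sample_region_set(spectral_grid(350, 360, 1, numeric(0)),
                                 min_width = 20), "min_width")
})

test_that("region subsetting selects closed intervals and merges overlaps", {
  g <- spectral_grid()
  s <- toy_spectra(rep(0.5, 2151), g)
  r1 <- region_set(matrix(c(350, 352), 1), g, min_width = 2)
  expect_equal(ncol(subset_by_regions(s, r1)), 3)
  expect_equal(colnames(subset_by_regions(s, r1)), c("350", "351", "352"))
  rfull <- full_spectrum_regions(g)
  expect_equal(subset_by_regions(s, rfull), s$values)
  # two intervals sharing a boundary merge; column set matches a
  # set-based oracle
  r2 <- region_set(list(c(400, 500), c(500, 600)), g)
  expect_equal(nrow(unclass(r2)), 1)
  wl <- grid_wavelengths(g)
  oracle_cols <- sort(unique(c(which(wl >= 400 & wl <= 500),
                               which(wl >= 500 & wl <= 600))))
  expect_equal(ncol(subset_by_regions(s, r2)), length(oracle_cols))
})

test_that("metric report matches the defining formulas", {
  perfect <- evaluate_model(c(1, 2, 3), c(1, 2, 3))
  expect_identical(perfect$r_squared, 1)
  expect_identical(perfect$rmsep, 0)
  e <- evaluate_model(c(1, 2, 3), c(2, 2, 2))
  expect_equal(e$rmsep, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(e$r_squared, 0, tolerance = 1e-12)
  expect_equal(e$n_validation, 3)
  expect_error(evaluate_model(c(1, 1), c(1, 2)), "zero observed variance")
  expect_error(evaluate_model(1:3, 1:2), "lengths differ")
})

test_that("F screen matches the deletion-variance formula", {
  # equal-magnitude residuals give F = 1 for every sample
  res <- c(1, -1, 1, -1, 1, -1)
  rep_ <- leafnirs:::outlier_f_report(res)
  expect_equal(rep_$f_value, rep(1, 6))
  expect_false(any(rep_$flagged))

  set.seed(40)
  res <- rnorm(50)
  res[7] <- 100 * sd(res)
  rep_ <- leafnirs:::outlier_f_report(res, 0.999)
  # direct recomputation of the formula
  f7 <- res[7]^2 / ((sum(res^2) - res[7]^2) / 49)
  expect_equal(rep_$f_value[7], f7)
  expect_equal(rep_$threshold[1], qf(0.999, 1, 48))
  expect_true(rep_$flagged[7])
  expect_false(any(rep_$removed))

  # flags are equivariant under sample relabeling
  perm <- sample(50)
  expect_equal(leafnirs:::outlier_f_report(res[perm])$flagged,
               rep_$flagged[perm])
})

test_that("detect_outliers works through a fitted model", {
  set.seed(41)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- drop(X %*% runif(5)) + rnorm(40, sd = 0.1)
  y[3] <- y[3] + 50
  m <- fit_plsr(X, y, 2)
  rep_ <- detect_outliers(X, y, m)
  expect_true(rep_$flagged[3])
  expect_error(detect_outliers(X[1:4, ], y[1:4], m), "at least 5")
})

test_that("optimizer keeps the best iteration and is fully reproducible", {
  cfg <- small_cfg(seed = 50)
  d <- generate_fertilization_experiment(cfg)
  dd <- splice_correct(average_replicates(d$dried))
  m1 <- optimize_calibration(dd, d$reference, trait = "leaf_N",
                             state = "dried", n_iterations = 8, seed = 99)
  # winner's RMSEP <= every evaluated candidate, including the baseline
  expect_true(all(m1$metrics$rmsep <= m1$iteration_log$rmsep + 1e-12))
  expect_equal(min(m1$iteration_log$rmsep), m1$metrics$rmsep)
  # same seed, same inputs -> byte-identical serialization
  m2 <- optimize_calibration(dd, d$reference, trait = "leaf_N",
                             state = "dried", n_iterations = 8, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_calibration(m1, f1); save_calibration(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # n_iterations = 0 returns the full-spectrum baseline
  m0 <- optimize_calibration(dd, d$reference, trait = "leaf_N",
                             state = "dried", n_iterations = 0, seed = 99)
  expect_equal(nrow(unclass(m0$regions)), 1)
  expect_equal(unclass(m0$regions)[1, ], c(start_nm = 350, end_nm = 2500))
})

test_that("saved models reload and predict bit-identically", {
  cfg <- small_cfg(seed = 51)
  d <- generate_fertilization_experiment(cfg)
  dd <- splice_correct(average_replicates(d$dried))
  m <- optimize_calibration(dd, d$reference, trait = "leaf_P",
                            state = "dried", n_iterations = 4, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  save_calibration(m, f)
  m2 <- load_calibration(f)
  p1 <- apply_model(m, dd)
  p2 <- apply_model(m2, dd)
  expect_identical(p1$predicted, p2$predicted)
  # natural-log models back-transform to strictly positive predictions
  mN <- optimize_calibration(dd, d$reference, trait = "leaf_N",
                             state = "dried", n_iterations = 0, seed = 7)
  expect_true(all(apply_model(mN, dd)$predicted > 0))
})

test_that("validation R2 is non-decreasing in trait band amplitude", {
  r2 <- vapply(c(0.1, 1, 4), function(mult) {
    cfg <- small_cfg(seed = 52)
    nb <- cfg$bands$driver == "leaf_N"
    cfg$bands$amplitude_per_unit[nb] <-
      cfg$bands$amplitude_per_unit[nb] * mult
    d <- generate_fertilization_experiment(cfg)
    dd <- splice_correct(average_replicates(d$dried))
    m <- optimize_calibration(dd, d$reference, trait = "leaf_N",
                              state = "dried", n_iterations = 6, seed = 1)
    m$metrics$r_squared
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-8))
})

test_that("outlier removal refits the winning configuration", {
  cfg <- small_cfg(seed = 53)
  d <- generate_fertilization_experiment(cfg)
  dd <- splice_correct(average_replicates(d$dried))
  ref <- d$reference
  # corrupt one assay value so the screen has something to flag
  ref$leaf_N[5] <- ref$leaf_N[5] * 40
  m <- optimize_calibration(dd, ref, trait = "leaf_N", state = "dried",
                            n_iterations = 0, seed = 3,
                            remove_outliers = TRUE)
  if (any(m$outliers$flagged)) {
    expect_true(all(m$outliers$removed == m$outliers$flagged))
  }
  expect_true(is.finite(m$metrics$rmsep))
})
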