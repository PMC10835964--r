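test_that("spectral grid arithmetic and validation", {
  g <- spectral_grid()
  expect_equal(length(grid_wavelengths(g)), 2151)
  expect_error(spectral_grid(500, 400), "start_nm")
  expect_error(spectral_grid(350, 2500, 3), "divide")
  expect_error(spectral_grid(splice_points_nm = c(1800, 1000)),
               "increasing")
  expect_error(spectral_grid(splice_points_nm = 2500), "inside")
})

test_that("read/write round trip preserves spectra in both layouts", {
  g <- spectral_grid(350, 360, 1, splice_points_nm = 355)
  set.seed(5)
  vals <- matrix(runif(4 * 11, 0.2, 0.9), 4, 11)
  meta <- data.frame(sample_id = c("a", "a", "b", "b"),
                     replicate = c(1L, 2L, 1L, 2L),
                     state = "fresh", group = NA_character_)
  s <- spectra_set(g, meta, vals)
  for (layout in c("wide", "long")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_spectra(s, f, layout)
    s2 <- read_spectra(f, layout, splice_points_nm = 355)
    expect_equal(s2$values, s$values)
    expect_equal(s2$meta$sample_id, s$meta$sample_id)
    expect_equal(grid_wavelengths(s2$grid), grid_wavelengths(s$grid))
  }
})

test_that("a 2-spectrum long file over the full grid parses to 2151 points", {
  wl <- 350:2500
  df <- data.frame(sample_id = rep(c("a", "b"), each = length(wl)),
                   replicate = 1L, state = "fresh", group = NA,
                   wavelength_nm = rep(wl, 2),
                   reflectance = rep(0.5, 2 * length(wl)))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  s <- read_spectra(f, "long")
  expect_equal(n_spectra(s), 2)
  expect_equal(grid_length(s$grid), 2151L)
})

test_that("invalid reflectance and ragged grids are rejected with context", {
  g <- spectral_grid(350, 352, 1, splice_points_nm = 351)
  expect_error(toy_spectra(c(0.5, 1.7, 0.5), g), "outside \\(0,1\\]")
  expect_error(toy_spectra(c(0.5, 0, 0.5), g), "outside")
  # ragged long file: one spectrum missing a wavelength
  df <- data.frame(sample_id = c("a", "a", "b"), replicate = 1L,
                   state = "fresh", wavelength_nm = c(350, 351, 350),
                   reflectance = 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_error(read_spectra(f, "long"), "ragged|grid")
})

test_that("replicate averaging is the arithmetic mean and is idempotent", {
  g <- spectral_grid(350, 351, 1, splice_points_nm = numeric(0))
  meta <- data.frame(sample_id = "a", replicate = 1:3, state = "fresh")
  s <- spectra_set(g, meta, cbind(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.9)))
  a <- average_replicates(s)
  expect_equal(n_spectra(a), 1)
  expect_equal(unname(a$values[1, ]), c(0.2, 0.6))
  expect_equal(a$meta$replicate, 1L)
  expect_equal(average_replicates(a)$values, a$values)
  # means stay within the replicate envelope at every wavelength
  expect_true(all(a$values >= apply(s$values, 2, min) - 1e-12))
  expect_true(all(a$values <= apply(s$values, 2, max) + 1e-12))
})

test_that("splice correction anchors on segment 1 and composes offsets", {
  g <- spectral_grid(996, 1005, 1, splice_points_nm = 1000)
  flat <- c(rep(0.50, 5), rep(0.55, 5))
  s <- toy_spectra(flat, g)
  out <- splice_correct(s)
  expect_equal(unname(out$values[1, ]), rep(0.50, 10))

  # two splices: +0.05 then -0.02 -> final segment net shift -0.03
  g2 <- spectral_grid(350, 364, 1, splice_points_nm = c(354, 359))
  raw <- c(rep(0.50, 5), rep(0.55, 5), rep(0.53, 5))
  out2 <- splice_correct(toy_spectra(raw, g2))
  expect_equal(unname(out2$values[1, ]), rep(0.50, 15))
  # recompute directly: segment 3 shifted by -(0.05) - (-0.02) = -0.03
  expect_equal(unname(out2$values[1, 15]), raw[15] - 0.03)

  # no step at either boundary (zero offsets): spectrum unchanged
  cont <- c(0.40, 0.42, 0.45, 0.45, 0.45, 0.45, 0.47, 0.50, 0.52, 0.52,
            0.52, 0.55, 0.58, 0.57, 0.56)
  expect_equal(splice_correct(toy_spectra(cont, g2))$values,
               toy_spectra(cont, g2)$values)
})

test_that("splice correction preserves within-segment differences and clips", {
  g <- spectral_grid(350, 369, 1, splice_points_nm = c(356, 363))
  set.seed(9)
  raw <- runif(20, 0.3, 0.7)
  s <- toy_spectra(raw, g)
  out <- splice_correct(s)
  segs <- list(1:7, 8:14, 15:20)
  for (seg in segs)
    expect_equal(diff(out$values[1, seg]), diff(s$values[1, seg]))
  # a downward step followed by a rising segment pushes values past 1
  low <- c(rep(0.95, 7), seq(0.5, 0.98, length.out = 13))
  expect_warning(out2 <- splice_correct(toy_spectra(low, g)), "clipped")
  expect_true(all(out2$values > 0 & out2$values <= 1))
  expect_error(splice_correct(s, splice_points_nm = 356.5), "off-grid")
})

test_that("reference table validation enforces the factorial level sets", {
  ref <- data.frame(sample_id = c("a", "b"), species = "x",
                    leaf_N = c(2, 3), leaf_P = c(1.5, 2),
                    fert_N_level = c(5, 200), fert_P_level = c(1, 40))
  f <- withr::local_tempfile(fileext = ".csv")
  write_reference(ref, f)
  expect_equal(read_reference(f)$leaf_N, c(2, 3))
  ref$fert_N_level[1] <- 50
  expect_error(leafnirs:::validate_reference(ref), "5, 20, 100, 200")
  ref$fert_N_level[1] <- 5; ref$leaf_P[1] <- -1
  expect_error(leafnirs:::validate_reference(ref), "leaf_P")
  ref$leaf_P[1] <- 1; ref$sample_id[2] <- "a"
  expect_error(leafnirs:::validate_reference(ref), "unique")
})
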