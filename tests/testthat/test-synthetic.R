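test_that("trait responses saturate, stay positive, and motivate the log", {
  cfg <- sim_config(seed = 70)
  set.seed(1)
  lo <- trait_response(rep(5, 200), rep(4, 200),
                       rep(cfg$species[1], 200), cfg)
  hi <- trait_response(rep(200, 200), rep(4, 200),
                       rep(cfg$species[1], 200), cfg)
  expect_gt(mean(hi$leaf_N), mean(lo$leaf_N))
  expect_true(all(lo$leaf_N > 0 & lo$leaf_P > 0))

  # zero biological noise lands exactly on the saturating curve
  cfg0 <- cfg
  cfg0$trait_params$N$noise_sdlog <- 0
  set.seed(1)
  t0 <- trait_response(100, 20, cfg$species[2], cfg0)
  tp <- cfg$trait_params$N
  expect_equal(t0$leaf_N, tp$baseline[2] + tp$gain[2] * 100 /
                 (tp$half_sat[2] + 100))

  # the log response over the default design is roughly symmetric
  d <- generate_fertilization_experiment(sim_config(seed = 71))
  expect_lt(abs(sample_skewness(log(d$truth$leaf_N))), 0.5)
})

test_that("the forward model places state and trait signal where expected", {
  cfg <- noiseless_cfg(seed = 72)
  fresh <- render_spectrum(2, 1.5, "fresh", cfg)
  dried <- render_spectrum(2, 1.5, "dried", cfg)
  wl <- grid_wavelengths(cfg$grid)
  # largest fresh/dried difference sits within 30 nm of a water band
  peak <- wl[which.max(abs(fresh - dried))]
  expect_true(min(abs(peak - c(1450, 1940))) <= 30)

  # doubling leaf N strictly deepens absorption at every N band center
  r1 <- render_spectrum(1.5, 1.5, "dried", cfg)
  r2 <- render_spectrum(3.0, 1.5, "dried", cfg)
  centers <- cfg$bands$center_nm[cfg$bands$driver == "leaf_N"]
  expect_true(all(r2[match(centers, wl)] < r1[match(centers, wl)]))

  # determinism: no noise, same traits -> identical spectra
  expect_identical(render_spectrum(2, 1.5, "dried", cfg),
                   render_spectrum(2, 1.5, "dried", cfg))
  expect_true(all(fresh > 0 & fresh <= 1))
})

test_that("fertilization design counts match the factorial layout", {
  d <- generate_fertilization_experiment(small_cfg(seed = 73))
  ref <- d$reference
  expect_equal(nrow(ref), 48)  # 3 species x 16 individuals
  expect_equal(nrow(unique(ref[, c("fert_N_level", "fert_P_level")])), 16)
  expect_equal(n_spectra(d$fresh), 48 * 2)  # 2 replicates in small_cfg
  expect_setequal(unique(d$fresh$meta$state), "fresh")
  expect_setequal(unique(d$dried$meta$state), "dried")

  full <- sim_config(seed = 73)
  expect_equal(full$individuals_per_species * length(full$species), 240)
  expect_error(sim_config(individuals_per_species = 15), "divisible")
})

test_that("generation is deterministic and assay noise is separable", {
  a <- generate_fertilization_experiment(small_cfg(seed = 74))
  b <- generate_fertilization_experiment(small_cfg(seed = 74))
  expect_identical(a$fresh$values, b$fresh$values)
  expect_identical(a$reference, b$reference)
  c_ <- generate_fertilization_experiment(small_cfg(seed = 75))
  expect_false(identical(a$fresh$values, c_$fresh$values))

  cfg0 <- small_cfg(seed = 74,
                    assay_sdlog = c(leaf_N = 0, leaf_P = 0))
  d0 <- generate_fertilization_experiment(cfg0)
  expect_equal(d0$reference$leaf_N, d0$truth$leaf_N)
  expect_equal(d0$reference$leaf_P, d0$truth$leaf_P)
})

test_that("treatment experiment matches the conservation design", {
  d <- generate_treatment_experiment(sim_config(seed = 76))
  ref <- d$reference
  expect_equal(nrow(ref), 40)
  tab <- table(ref$group)
  expect_equal(unname(tab["control"]), 10)
  expect_equal(length(tab), 7)  # six treatments + control -> df = 6
  expect_true(all(tab[names(tab) != "control"] == 5))

  # null treatment with all noise off: treated spectra equal dried
  cfg0 <- noiseless_cfg(seed = 76)
  d0 <- generate_treatment_experiment(cfg0)
  expect_equal(d0$treated$values, d0$dried$values, tolerance = 1e-12)

  cfg_bad <- sim_config(seed = 76)
  cfg_bad$treatment$group_size <- 10
  expect_error(generate_treatment_experiment(cfg_bad), "exceed")
})

test_that("a concentrated treatment effect shifts only the target group", {
  cfg <- noiseless_cfg(seed = 77)
  cfg$treatment$effect_size <- 0.05
  d <- generate_treatment_experiment(cfg)
  row_group <- d$truth$group[match(d$treated$meta$sample_id,
                                   d$truth$sample_id)]
  hit <- row_group == cfg$treatment$effect_group
  dif <- rowMeans(abs(d$treated$values - d$dried$values))
  expect_gt(min(dif[hit]), max(dif[!hit]))
})

test_that("storage re-scan drifts exactly as configured", {
  cfg0 <- noiseless_cfg(seed = 78)
  d0 <- generate_storage_experiment(cfg0)
  expect_equal(d0$scan_t0$values, d0$scan_t1$values, tolerance = 1e-12)
  expect_setequal(unique(d0$scan_t1$meta$state), "rescanned")

  cfg1 <- noiseless_cfg(seed = 78)
  cfg1$storage$drift_sd <- 0.05
  d1 <- generate_storage_experiment(cfg1)
  expect_gt(mean(abs(d1$scan_t0$values - d1$scan_t1$values)), 0)
  # drift targets t0 by default: t1 matches the undrifted render
  expect_equal(d1$scan_t1$values, d0$scan_t1$values, tolerance = 1e-12)
})
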