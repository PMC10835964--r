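# Independent oracles and small fixtures used across the test files.

# Exhaustive greedy max-min Kennard-Stone reimplementation: recomputes all
# pairwise distances and the argmax at every step with plain loops, using
# the same documented tie rules (lexicographically smallest seed pair,
# later ties toward the smaller row index).
ks_oracle <- function(X, fraction = 0.5) {
  n <- nrow(X)
  k <- max(2L, as.integer(floor(fraction * n + 0.5)))
  d2 <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(NA, NA); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- d2(i, j)
    if (dij > bestd) { bestd <- dij; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(c.) min(sapply(sel, function(s) d2(c., s))))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}

sample_skewness <- function(z) mean((z - mean(z))^3) / stats::sd(z)^3

# small synthetic design for fast end-to-end tests
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, individuals_per_species = 16,
             replicate_count = 2, ...)
}

# config with every stochastic term switched off
noiseless_cfg <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, noise_sd = 0, scatter_sd = 0,
                    splice_step_sd = 0,
                    assay_sdlog = c(leaf_N = 0, leaf_P = 0), ...)
  cfg$trait_params$N$noise_sdlog <- 0
  cfg$trait_params$P$noise_sdlog <- 0
  cfg$treatment$leaf_perturb_sd <- 0
  cfg$storage$drift_sd <- 0
  cfg
}

# tiny spectra_set fixture on a short grid
toy_spectra <- function(values, grid = spectral_grid(350, 360, 1,
                                                     splice_points_nm = 355),
                        state = "fresh") {
  values <- matrix(values, ncol = grid_length(grid), byrow = TRUE)
  meta <- data.frame(sample_id = paste0("s", seq_len(nrow(values))),
                     replicate = 1L, state = state)
  spectra_set(grid, meta, values)
}

grid_length <- leafnirs:::grid_length
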