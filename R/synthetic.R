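#' Configuration of the synthetic experiments
#'
#' Full parameterization of the synthetic spectra generator, which emulates
#' the three study designs end to end: a greenhouse fertilization
#' experiment (3 species x 4 N-levels x 4 P-levels, 80 individuals per
#' species, paired fresh and pressed-dried scans, 3 replicates on the same
#' spot), a herbarium conservation-treatment experiment (40 specimens of
#' one species, six treatment groups of five plus untreated controls, with
#' a null chemical effect by default), and a storage experiment (re-scan of
#' the same dried specimens in a later session by a different operator,
#' modelled as session drift).
#'
#' The forward model is Beer-Lambert-like: absorbance is a smooth baseline
#' plus Gaussian bands whose depths scale with the driving quantity (leaf
#' N, leaf P, or leaf water), and reflectance is `10^(-A)` times a per-scan
#' affine scatter term, plus instrument noise, plus small per-detector step
#' offsets at the splice points. Water bands (1450/1940 nm) dominate fresh
#' leaves and shrink on drying; P bands are intrinsically weaker than N
#' bands, so phosphorus calibrations are harder, as with real leaves where
#' P is the scarcer element. Wet-lab reference values are the generator's
#' ground-truth traits times an independent assay noise, so calibration
#' quality is bounded below 1 even with perfect spectra.
#'
#' @param seed Integer seed; every generated number derives from it.
#' @param grid A [spectral_grid()].
#' @param species Species labels (default the study's three grassland
#'   species, chosen for contrasting leaf shapes).
#' @param individuals_per_species Default 80; must be divisible by the 16
#'   fertilization combinations.
#' @param fert_N_levels,fert_P_levels Factorial fertilization levels in
#'   kg ha-1 yr-1 (defaults 5/20/100/200 and 1/4/20/40).
#' @param trait_params Per-species saturating response parameters: lists
#'   `N` and `P`, each with `baseline`, `gain`, `half_sat` vectors (one per
#'   species) and `noise_sdlog` (biological lognormal scatter). Leaf N is
#'   in % dry mass, leaf P in mg/g dry mass; the P response has the smaller
#'   relative gain (its response to fertilization is less pronounced).
#' @param bands Band library: data.frame with `center_nm`, `width_nm`
#'   (Gaussian sigma), `amplitude_per_unit` (absorbance per driver unit),
#'   `driver` (`leaf_N`, `leaf_P`, `water`, `constant`).
#' @param water_content Named per-state leaf water driver values.
#' @param baseline Baseline absorbance coefficients `c(intercept, slope,
#'   curvature)` over the normalized wavelength axis.
#' @param noise_sd Additive reflectance noise sd per scan.
#' @param scatter_sd Per-scan multiplicative affine scatter: sd of slope
#'   and offset.
#' @param splice_step_sd Sd of the per-scan additive reflectance offset of
#'   each detector segment after the first (what splice correction removes).
#' @param replicate_count Scans per leaf (default 3).
#' @param assay_sdlog Named lognormal sd of the wet-lab assay noise for
#'   `leaf_N` and `leaf_P`.
#' @param treatment Conservation-treatment design: `n_specimens`, `groups`,
#'   `group_size`, `n_control`, `effect_size` (absorbance at the effect
#'   band per treated leaf; default 0 = null chemical effect),
#'   `effect_group` (which group carries the effect when nonzero),
#'   `effect_center_nm`, `effect_width_nm`, and `leaf_perturb_sd`
#'   (idiosyncratic smooth per-leaf absorbance perturbation of treated
#'   leaves).
#' @param storage Storage re-scan design: `n_specimens`, `drift_sd`
#'   (operator/session affine drift: one session-common component plus a
#'   per-sample probe-placement component, both with this sd), and
#'   `drift_target` (`"t0"` or `"t1"`: which session the drifting operator
#'   scanned; default `"t0"`, the earlier session).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(
    seed = 1,
    grid = spectral_grid(),
    species = c("Centaurea_jacea", "Plantago_lanceolata", "Poa_annua"),
    individuals_per_species = 80,
    fert_N_levels = c(5, 20, 100, 200),
    fert_P_levels = c(1, 4, 20, 40),
    trait_params = list(
      N = list(baseline = c(1.0, 1.1, 0.9), gain = c(2.8, 2.6, 2.4),
               half_sat = c(60, 60, 60), noise_sdlog = 0.08),
      P = list(baseline = c(1.2, 1.3, 1.1), gain = c(1.2, 1.1, 1.0),
               half_sat = c(12, 12, 12), noise_sdlog = 0.10)),
    bands = data.frame(
      center_nm = c(1510, 2054, 2180, 1680, 2380, 1450, 1940, 1200, 2280),
      width_nm = c(30, 35, 40, 25, 30, 45, 55, 60, 35),
      amplitude_per_unit = c(0.050, 0.060, 0.045, 0.0045, 0.0035,
                             0.30, 0.50, 0.08, 0.05),
      driver = c("leaf_N", "leaf_N", "leaf_N", "leaf_P", "leaf_P",
                 "water", "water", "constant", "constant"),
      stringsAsFactors = FALSE),
    water_content = c(fresh = 1.0, dried = 0.12, treated = 0.12,
                      rescanned = 0.12),
    baseline = c(0.25, 0.20, 0.10),
    noise_sd = 0.002,
    scatter_sd = 0.010,
    splice_step_sd = 0.003,
    replicate_count = 3,
    assay_sdlog = c(leaf_N = 0.20, leaf_P = 0.16),
    treatment = list(
      n_specimens = 40,
      groups = c("freezing", "drying", "pesticide", "freezing_drying",
                 "freezing_pesticide", "freezing_drying_pesticide"),
      group_size = 5, n_control = 10,
      effect_size = 0, effect_group = "freezing",
      effect_center_nm = 1730, effect_width_nm = 40,
      leaf_perturb_sd = 0.010),
    storage = list(n_specimens = 40, drift_sd = 0.4,
                   drift_target = "t0")) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (length(fert_N_levels) == 0 || length(fert_P_levels) == 0)
    stop("fertilization level sets must be nonempty")
  if (noise_sd < 0 || scatter_sd < 0 || splice_step_sd < 0)
    stop("noise parameters must be >= 0")
  n_comb <- length(fert_N_levels) * length(fert_P_levels)
  if (individuals_per_species %% n_comb != 0)
    stop(sprintf(paste("configuration error: individuals_per_species (%d)",
                       "not divisible across the %d level combinations"),
         individuals_per_species, n_comb))
  cfg <- mget(names(formals(sim_config)))
  structure(cfg, class = "sim_config")
}

#' Saturating trait response to fertilization
#'
#' Ground-truth leaf traits follow a Michaelis-Menten-type saturating
#' response to the fertilization dose, with species-specific parameters
#' and multiplicative lognormal biological scatter:
#' `trait = (a_s + b_s * F / (K_s + F)) * exp(noise)`. Leaf N responds
#' more strongly (larger relative gain) than leaf P. Uses the current RNG
#' state. Strictly positive by construction.
#'
#' @param fert_N,fert_P Fertilization doses (vectors, kg ha-1 yr-1).
#' @param species Species labels aligned with the doses.
#' @param cfg A [sim_config()].
#' @return data.frame with columns `leaf_N` (% dry mass) and `leaf_P`
#'   (mg/g dry mass).
#' @export
trait_response <- function(fert_N, fert_P, species, cfg) {
  si <- match(species, cfg$species)
  if (any(is.na(si))) stop("unknown species")
  n <- length(fert_N)
  tp <- cfg$trait_params
  leaf_N <- (tp$N$baseline[si] + tp$N$gain[si] * fert_N /
               (tp$N$half_sat[si] + fert_N)) *
    exp(stats::rnorm(n, 0, tp$N$noise_sdlog))
  leaf_P <- (tp$P$baseline[si] + tp$P$gain[si] * fert_P /
               (tp$P$half_sat[si] + fert_P)) *
    exp(stats::rnorm(n, 0, tp$P$noise_sdlog))
  data.frame(leaf_N = leaf_N, leaf_P = leaf_P)
}

# Gaussian band profiles on the grid: matrix n_wl x n_bands
band_profiles <- function(cfg) {
  wl <- grid_wavelengths(cfg$grid)
  vapply(seq_len(nrow(cfg$bands)), function(i)
    exp(-0.5 * ((wl - cfg$bands$center_nm[i]) / cfg$bands$width_nm[i])^2),
    numeric(length(wl)))
}

# deterministic absorbance for one leaf in one state
absorbance_clean <- function(leaf_N, leaf_P, state, cfg, profiles) {
  wl <- grid_wavelengths(cfg$grid)
  xn <- (wl - cfg$grid$start_nm) / (cfg$grid$end_nm - cfg$grid$start_nm)
  base <- cfg$baseline[1] + cfg$baseline[2] * xn + cfg$baseline[3] * xn^2
  driver_value <- c(leaf_N = leaf_N, leaf_P = leaf_P,
                    water = unname(cfg$water_content[state]), constant = 1)
  amps <- cfg$bands$amplitude_per_unit * driver_value[cfg$bands$driver]
  base + drop(profiles %*% amps)
}

# one scan: scatter, noise, detector steps; uses the current RNG state
scan_from_absorbance <- function(A, cfg, extra_affine = c(0, 0)) {
  wl <- grid_wavelengths(cfg$grid)
  n_wl <- length(wl)
  xc <- (wl - mean(wl)) / (cfg$grid$end_nm - cfg$grid$start_nm)
  slope <- stats::rnorm(1, 0, cfg$scatter_sd) + extra_affine[1]
  offset <- stats::rnorm(1, 0, cfg$scatter_sd) + extra_affine[2]
  refl <- 10^(-A) * (1 + slope * xc + offset)
  sp <- cfg$grid$splice_points_nm
  if (length(sp)) {
    steps <- stats::rnorm(length(sp), 0, cfg$splice_step_sd)
    for (k in seq_along(sp)) {
      refl[wl > sp[k]] <- refl[wl > sp[k]] + steps[k]
    }
  }
  refl <- refl + stats::rnorm(n_wl, 0, cfg$noise_sd)
  pmin(pmax(refl, 1e-6), 1)
}

#' Render one synthetic reflectance spectrum
#'
#' Forward model for a single scan (one replicate) of one leaf: Gaussian
#' absorption bands scaled by the leaf's traits and state-dependent water
#' content on a smooth baseline, converted to reflectance with per-scan
#' affine scatter, detector step offsets at the splice points, and
#' additive noise. Uses the current RNG state; with all noise parameters
#' zero the output is a deterministic function of the traits.
#'
#' @param leaf_N,leaf_P Trait values of the leaf.
#' @param state Leaf state (`"fresh"`, `"dried"`, `"treated"`,
#'   `"rescanned"`).
#' @param cfg A [sim_config()].
#' @return Numeric reflectance vector on the grid, in (0, 1].
#' @export
render_spectrum <- function(leaf_N, leaf_P, state, cfg) {
  stopifnot(leaf_N > 0, leaf_P > 0)
  profiles <- band_profiles(cfg)
  A <- absorbance_clean(leaf_N, leaf_P, state, cfg, profiles)
  scan_from_absorbance(A, cfg)
}

# render replicate scans for a table of leaves; absorb_extra is an optional
# per-leaf additive absorbance matrix (n_leaves rows)
render_state <- function(traits, state, cfg, profiles,
                         absorb_extra = NULL, extra_affine = NULL,
                         replicate_count = cfg$replicate_count) {
  n <- nrow(traits)
  n_wl <- grid_length(cfg$grid)
  values <- matrix(0, n * replicate_count, n_wl)
  meta <- data.frame(
    sample_id = rep(traits$sample_id, each = replicate_count),
    replicate = rep(seq_len(replicate_count), times = n),
    state = state,
    group = rep(if ("group" %in% names(traits)) traits$group
                else NA_character_, each = replicate_count),
    stringsAsFactors = FALSE)
  row <- 1L
  for (i in seq_len(n)) {
    A <- absorbance_clean(traits$leaf_N[i], traits$leaf_P[i], state, cfg,
                          profiles)
    if (!is.null(absorb_extra)) A <- A + absorb_extra[i, ]
    aff <- if (is.null(extra_affine)) c(0, 0) else extra_affine[i, ]
    for (r in seq_len(replicate_count)) {
      values[row, ] <- scan_from_absorbance(A, cfg, aff)
      row <- row + 1L
    }
  }
  spectra_set(cfg$grid, meta, values)
}

# ground truth -> wet-lab assay values (independent lognormal assay noise)
assay_reference <- function(traits, cfg) {
  n <- nrow(traits)
  data.frame(
    sample_id = traits$sample_id,
    species = traits$species,
    leaf_N = traits$leaf_N * exp(stats::rnorm(n, 0, cfg$assay_sdlog["leaf_N"])),
    leaf_P = traits$leaf_P * exp(stats::rnorm(n, 0, cfg$assay_sdlog["leaf_P"])),
    stringsAsFactors = FALSE)
}

#' Generate the synthetic fertilization experiment
#'
#' Emulates the greenhouse design: each species' individuals are spread
#' evenly over the 4 x 4 factorial of N and P fertilization levels (16
#' combinations), ground-truth traits follow the saturating response, and
#' each individual is scanned fresh and again after pressing/drying, with
#' `replicate_count` scans each. The reference table carries wet-lab-style
#' assay values (ground truth x assay noise) plus the design factors.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `fresh` and `dried` ([spectra_set()]s),
#'   `reference` (data.frame), and `truth` (the noiseless ground-truth
#'   traits, for validation studies).
#' @export
generate_fertilization_experiment <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  combos <- expand.grid(fert_N = cfg$fert_N_levels,
                        fert_P = cfg$fert_P_levels)
  per_combo <- cfg$individuals_per_species / nrow(combos)
  design <- do.call(rbind, lapply(cfg$species, function(sp) {
    data.frame(species = sp,
               fert_N_level = rep(combos$fert_N, each = per_combo),
               fert_P_level = rep(combos$fert_P, each = per_combo),
               stringsAsFactors = FALSE)
  }))
  design$sample_id <- sprintf("F%03d", seq_len(nrow(design)))
  tr <- trait_response(design$fert_N_level, design$fert_P_level,
                       design$species, cfg)
  traits <- cbind(design, tr)
  profiles <- band_profiles(cfg)
  fresh <- render_state(traits, "fresh", cfg, profiles)
  dried <- render_state(traits, "dried", cfg, profiles)
  reference <- assay_reference(traits, cfg)
  reference$fert_N_level <- traits$fert_N_level
  reference$fert_P_level <- traits$fert_P_level
  list(fresh = fresh, dried = dried,
       reference = validate_reference(reference),
       truth = traits)
}

#' Generate the synthetic conservation-treatment experiment
#'
#' Emulates the herbarium-conservation design: `n_specimens` flowering
#' specimens of one species, scanned fresh, after pressing/drying, and
#' after a conservation treatment. Six treatment groups (combinations of
#' freezing, drying at 60 C, and pesticide application) of `group_size`
#' each, plus `n_control` untreated controls, give seven groups. The
#' treatment's chemical effect defaults to zero — treated spectra differ
#' from dried only by idiosyncratic smooth per-leaf perturbations and scan
#' noise — encoding a null treatment effect; `effect_size > 0` adds an
#' absorption feature to one group for power studies.
#'
#' @param cfg A [sim_config()].
#' @return List with `fresh`, `dried`, `treated` ([spectra_set()]s, groups
#'   recorded in the metadata and reference), `reference`, `truth`.
#' @export
generate_treatment_experiment <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  tcfg <- cfg$treatment
  n <- tcfg$n_specimens
  n_treated <- length(tcfg$groups) * tcfg$group_size
  if (n_treated + tcfg$n_control > n)
    stop("configuration error: group sizes exceed specimen count")
  group <- c(rep(tcfg$groups, each = tcfg$group_size),
             rep("control", n - n_treated))
  sp <- cfg$species[min(2, length(cfg$species))]  # the intermediate-leaf one
  # field-collected population: traits around a mid-range dose response
  mid_N <- stats::median(cfg$fert_N_levels)
  mid_P <- stats::median(cfg$fert_P_levels)
  tr <- trait_response(rep(mid_N, n), rep(mid_P, n), rep(sp, n), cfg)
  traits <- data.frame(sample_id = sprintf("T%03d", seq_len(n)),
                       species = sp, group = group, tr,
                       stringsAsFactors = FALSE)
  profiles <- band_profiles(cfg)
  fresh <- render_state(traits, "fresh", cfg, profiles)
  dried <- render_state(traits, "dried", cfg, profiles)
  # treated: dried chemistry + per-leaf smooth perturbation + group effect
  wl <- grid_wavelengths(cfg$grid)
  extra <- matrix(0, n, length(wl))
  if (tcfg$leaf_perturb_sd > 0) {
    centers <- stats::runif(n, cfg$grid$start_nm + 100,
                            cfg$grid$end_nm - 100)
    amps <- stats::rnorm(n, 0, tcfg$leaf_perturb_sd)
    widths <- stats::runif(n, 50, 200)
    for (i in seq_len(n))
      extra[i, ] <- amps[i] * exp(-0.5 * ((wl - centers[i]) / widths[i])^2)
  }
  if (tcfg$effect_size != 0) {
    hit <- traits$group == tcfg$effect_group
    eff <- tcfg$effect_size *
      exp(-0.5 * ((wl - tcfg$effect_center_nm) / tcfg$effect_width_nm)^2)
    extra[hit, ] <- extra[hit, ] + rep(eff, each = sum(hit))
  }
  treated <- render_state(traits, "treated", cfg, profiles,
                          absorb_extra = extra)
  reference <- assay_reference(traits, cfg)
  reference$group <- traits$group
  list(fresh = fresh, dried = dried, treated = treated,
       reference = validate_reference(reference), truth = traits)
}

#' Generate the synthetic storage (re-scan) experiment
#'
#' Emulates scanning the same dried specimens in two sessions years apart:
#' leaf chemistry is unchanged, but each session has its own scan noise,
#' and the session scanned by a different operator (default the earlier
#' one, `t0`) additionally carries operator drift — a session-common
#' affine distortion plus a per-sample probe-placement distortion, both of
#' sd `storage$drift_sd`. The per-sample component is what degrades the
#' between-session prediction correlation.
#'
#' @param cfg A [sim_config()].
#' @return List with `scan_t0` (state `"dried"`), `scan_t1` (state
#'   `"rescanned"`), `reference`, `truth`.
#' @export
generate_storage_experiment <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 2L)
  scfg <- cfg$storage
  n <- scfg$n_specimens
  sp <- cfg$species[min(2, length(cfg$species))]
  mid_N <- stats::median(cfg$fert_N_levels)
  mid_P <- stats::median(cfg$fert_P_levels)
  tr <- trait_response(rep(mid_N, n), rep(mid_P, n), rep(sp, n), cfg)
  traits <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                       species = sp, tr, stringsAsFactors = FALSE)
  profiles <- band_profiles(cfg)
  drift <- function() {
    common <- stats::rnorm(2, 0, scfg$drift_sd)
    t(vapply(seq_len(n), function(i)
      common + stats::rnorm(2, 0, scfg$drift_sd), numeric(2)))
  }
  zero <- matrix(0, n, 2)
  aff_t0 <- if (identical(scfg$drift_target, "t0") && scfg$drift_sd > 0)
    drift() else zero
  aff_t1 <- if (identical(scfg$drift_target, "t1") && scfg$drift_sd > 0)
    drift() else zero
  scan_t0 <- render_state(traits, "dried", cfg, profiles,
                          extra_affine = aff_t0)
  scan_t1 <- render_state(traits, "rescanned", cfg, profiles,
                          extra_affine = aff_t1)
  reference <- assay_reference(traits, cfg)
  list(scan_t0 = scan_t0, scan_t1 = scan_t1,
       reference = validate_reference(reference), truth = traits)
}
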