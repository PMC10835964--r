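#' Derive per-stage seeds from a master seed
#'
#' The pipeline fans one master seed out to its stages by seeding R's RNG
#' with the master seed and drawing one 31-bit integer per stage; stage
#' `i` always receives the `i`-th draw, so adding stages never perturbs
#' earlier ones.
#'
#' @param master Integer master seed.
#' @param n Number of stage seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n = 8) {
  set.seed(as.integer(master) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# shared preprocessing: average the replicate scans, remove detector steps
preprocess <- function(s) splice_correct(average_replicates(s))

#' Run the fertilization experiment analysis
#'
#' Generates (or accepts) the fertilization data, preprocesses the spectra
#' (replicate averaging, splice correction), and fits the four calibration
#' models: leaf N and leaf P, each on fresh and on dried leaves. Leaf N is
#' calibrated on the natural-log scale; metrics are reported on the
#' model's working scale. Optionally writes the four model JSONs, the
#' iteration logs, and a metrics CSV.
#'
#' @param cfg A [sim_config()].
#' @param n_iterations Region-search iterations per model.
#' @param data Optional pre-generated data list (as returned by
#'   [generate_fertilization_experiment()]); generated from `cfg` when
#'   `NULL`.
#' @param out_dir Optional output directory for artifacts.
#' @param per_species If `TRUE`, add a per-species validation metric
#'   breakdown for each model.
#' @return List of class `"experiment_report"`: `models` (named list of
#'   `"calibration_model"`), `metrics` (data.frame: trait, state,
#'   r_squared, rmsep, n_validation), optional `species_metrics`, `config`
#'   echo, `files`.
#' @export
run_experiment1 <- function(cfg = sim_config(), n_iterations = 200,
                            data = NULL, out_dir = NULL,
                            per_species = FALSE) {
  if (is.null(data)) data <- generate_fertilization_experiment(cfg)
  seeds <- derive_seeds(cfg$seed, 8)
  sets <- list(fresh = preprocess(data$fresh),
               dried = preprocess(data$dried))
  spec <- expand.grid(trait = c("leaf_N", "leaf_P"),
                      state = c("fresh", "dried"),
                      stringsAsFactors = FALSE)
  models <- vector("list", nrow(spec))
  names(models) <- paste(spec$trait, spec$state, sep = "_")
  for (i in seq_len(nrow(spec))) {
    models[[i]] <- optimize_calibration(
      sets[[spec$state[i]]], data$reference, trait = spec$trait[i],
      state = spec$state[i], n_iterations = n_iterations,
      seed = seeds[i])
  }
  metrics <- data.frame(
    trait = spec$trait, state = spec$state,
    transform = vapply(models, function(m) m$transform, character(1)),
    r_squared = vapply(models, function(m) m$metrics$r_squared, numeric(1)),
    rmsep = vapply(models, function(m) m$metrics$rmsep, numeric(1)),
    n_validation = vapply(models, function(m)
      as.integer(m$metrics$n_validation), integer(1)),
    row.names = NULL)
  report <- list(experiment = "fertilization", models = models,
                 metrics = metrics, seed = cfg$seed, files = character(0))
  if (per_species)
    report$species_metrics <- species_breakdown(models, sets,
                                                data$reference)
  if (!is.null(out_dir)) report$files <- write_report1(report, out_dir)
  class(report) <- "experiment_report"
  report
}

# validation metrics recomputed within each species
species_breakdown <- function(models, sets, reference) {
  do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    s <- sets[[m$state]]
    preds <- apply_model(m, s)
    val <- preds$sample_id %in% m$split$validation_ids
    preds <- preds[val, ]
    ref_idx <- match(preds$sample_id, reference$sample_id)
    obs <- transform_response(reference[[m$trait]][ref_idx], m$transform)
    pred <- transform_response(preds$predicted, m$transform)
    sp <- reference$species[ref_idx]
    do.call(rbind, lapply(split(seq_along(obs), sp), function(ix) {
      met <- evaluate_model(obs[ix], pred[ix])
      data.frame(model = nm, trait = m$trait, state = m$state,
                 species = sp[ix[1]], r_squared = met$r_squared,
                 rmsep = met$rmsep, n = length(ix))
    }))
  }))
}

write_report1 <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(report$models)) {
    f <- file.path(out_dir, paste0("model_", nm, ".json"))
    save_calibration(report$models[[nm]], f)
    flog <- file.path(out_dir, paste0("iterations_", nm, ".csv"))
    utils::write.csv(report$models[[nm]]$iteration_log, flog,
                     row.names = FALSE)
    files <- c(files, f, flog)
  }
  fm <- file.path(out_dir, "experiment1_metrics.csv")
  utils::write.csv(report$metrics, fm, row.names = FALSE)
  c(files, fm)
}

#' Run the conservation-treatment experiment analysis
#'
#' Applies the dried-leaf nitrogen reference calibration model to the
#' fresh, dried, and treated spectra of the treatment experiment, then
#' (a) compares predicted leaf N across the treatment groups (treated
#' spectra) with a Kruskal-Wallis test, following up with Dunn's test only
#' when significant, and (b) compares the four value sources — predictions
#' from fresh, dried, and treated spectra, and the laboratory reference —
#' with a second Kruskal-Wallis test and the same Dunn rule.
#'
#' @param cfg A [sim_config()].
#' @param reference_model The dried-leaf leaf_N `"calibration_model"`
#'   (from [run_experiment1()]).
#' @param data Optional pre-generated treatment data.
#' @param out_dir Optional output directory.
#' @param alpha Significance level gating the Dunn follow-up (0.05).
#' @return List of class `"experiment_report"`: `predictions` (long
#'   data.frame: sample_id, source, group, value), `kw_treatment`,
#'   `dunn_treatment` (NULL unless KW significant), `kw_sources`,
#'   `dunn_sources`, `files`.
#' @export
run_experiment2 <- function(cfg = sim_config(), reference_model,
                            data = NULL, out_dir = NULL, alpha = 0.05) {
  stopifnot(inherits(reference_model, "calibration_model"))
  if (is.null(data)) data <- generate_treatment_experiment(cfg)
  pred <- lapply(list(fresh = data$fresh, dried = data$dried,
                      treated = data$treated),
                 function(s) apply_model(reference_model, preprocess(s)))
  ref <- data$reference
  predictions <- rbind(
    data.frame(sample_id = pred$fresh$sample_id, source = "fresh",
               group = pred$fresh$group, value = pred$fresh$predicted),
    data.frame(sample_id = pred$dried$sample_id, source = "dried",
               group = pred$dried$group, value = pred$dried$predicted),
    data.frame(sample_id = pred$treated$sample_id, source = "treated",
               group = pred$treated$group, value = pred$treated$predicted),
    data.frame(sample_id = ref$sample_id, source = "laboratory",
               group = ref$group, value = ref$leaf_N))

  treated <- predictions[predictions$source == "treated", ]
  kw_treatment <- kruskal_wallis(treated$value, treated$group)
  dunn_treatment <- if (kw_treatment$p_value < alpha)
    dunn_test(treated$value, treated$group) else NULL
  kw_sources <- kruskal_wallis(predictions$value, predictions$source)
  dunn_sources <- if (kw_sources$p_value < alpha)
    dunn_test(predictions$value, predictions$source) else NULL

  report <- list(experiment = "treatment", predictions = predictions,
                 kw_treatment = kw_treatment,
                 dunn_treatment = dunn_treatment,
                 kw_sources = kw_sources, dunn_sources = dunn_sources,
                 seed = cfg$seed, files = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, "experiment2_predictions.csv")
    utils::write.csv(predictions, f, row.names = FALSE)
    report$files <- f
  }
  class(report) <- "experiment_report"
  report
}

#' Run the storage (re-scan) experiment analysis
#'
#' Predicts leaf N from the two scan sessions of the same dried specimens
#' through the reference calibration model and reports the three Pearson
#' correlations: between the two sessions' predictions, and between each
#' session's predictions and the laboratory reference values.
#'
#' @param cfg A [sim_config()].
#' @param reference_model The dried-leaf leaf_N `"calibration_model"`.
#' @param data Optional pre-generated storage data.
#' @param out_dir Optional output directory.
#' @return List of class `"experiment_report"`: `predictions` (wide
#'   data.frame: sample_id, pred_t0, pred_t1, laboratory), `correlations`
#'   (named: t0_t1, t0_lab, t1_lab), `files`.
#' @export
run_experiment3 <- function(cfg = sim_config(), reference_model,
                            data = NULL, out_dir = NULL) {
  stopifnot(inherits(reference_model, "calibration_model"))
  if (is.null(data)) data <- generate_storage_experiment(cfg)
  p0 <- apply_model(reference_model, preprocess(data$scan_t0))
  p1 <- apply_model(reference_model, preprocess(data$scan_t1))
  ref <- data$reference
  df <- data.frame(sample_id = p0$sample_id,
                   pred_t0 = p0$predicted,
                   pred_t1 = p1$predicted[match(p0$sample_id,
                                                p1$sample_id)],
                   laboratory = ref$leaf_N[match(p0$sample_id,
                                                 ref$sample_id)])
  correlations <- c(t0_t1 = pearson_cor(df$pred_t0, df$pred_t1),
                    t0_lab = pearson_cor(df$pred_t0, df$laboratory),
                    t1_lab = pearson_cor(df$pred_t1, df$laboratory))
  report <- list(experiment = "storage", predictions = df,
                 correlations = correlations, seed = cfg$seed,
                 files = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(out_dir, "experiment3_predictions.csv")
    utils::write.csv(df, f, row.names = FALSE)
    report$files <- f
  }
  class(report) <- "experiment_report"
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", x$experiment, "\n")
  if (!is.null(x$metrics)) print(x$metrics)
  if (!is.null(x$kw_treatment)) {
    cat("  treatment groups: "); print(x$kw_treatment)
    cat("  value sources:    "); print(x$kw_sources)
  }
  if (!is.null(x$correlations)) print(round(x$correlations, 3))
  invisible(x)
}

#' Run all three experiments under one master seed
#'
#' Full replication driver: generates the fertilization data and fits the
#' four calibrations, then reuses the dried-leaf nitrogen model as the
#' reference calibration model for the treatment and storage experiments
#' (the same chain of reuse as the study workflow). The master seed fans
#' out to the stages via [derive_seeds()], so a rerun with the same seed
#' reproduces every artifact byte for byte.
#'
#' @param cfg A [sim_config()]; its `seed` is overridden by `seed`.
#' @param seed Master seed.
#' @param n_iterations Region-search iterations per calibration model.
#' @param out_dir Optional artifact directory (model JSONs, prediction
#'   CSVs, a JSON summary).
#' @return List of class `"run_all_report"` with `experiment1`,
#'   `experiment2`, `experiment3`, `seed`, `files`.
#' @export
run_all <- function(cfg = sim_config(), seed = cfg$seed,
                    n_iterations = 200, out_dir = NULL) {
  cfg$seed <- as.integer(seed)
  e1 <- run_experiment1(cfg, n_iterations = n_iterations,
                        out_dir = out_dir)
  refmod <- e1$models$leaf_N_dried
  e2 <- run_experiment2(cfg, refmod, out_dir = out_dir)
  e3 <- run_experiment3(cfg, refmod, out_dir = out_dir)
  report <- list(experiment1 = e1, experiment2 = e2, experiment3 = e3,
                 seed = cfg$seed,
                 files = c(e1$files, e2$files, e3$files))
  if (!is.null(out_dir)) {
    summary <- list(
      seed = cfg$seed,
      experiment1 = e1$metrics,
      experiment2 = list(
        kw_treatment_h = e2$kw_treatment$h_statistic,
        kw_treatment_df = e2$kw_treatment$df,
        kw_treatment_p = e2$kw_treatment$p_value,
        kw_sources_h = e2$kw_sources$h_statistic,
        kw_sources_df = e2$kw_sources$df,
        kw_sources_p = e2$kw_sources$p_value),
      experiment3 = as.list(e3$correlations))
    f <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    report$files <- c(report$files, f)
  }
  class(report) <- "run_all_report"
  report
}
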