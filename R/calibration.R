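#' Transform a trait response
#'
#' Calibrations assume an approximately normal reference trait; strongly
#' right-skewed traits (leaf nitrogen under a saturating fertilization
#' design) are modelled on the natural-log scale and predictions
#' back-transformed. `natural_log` requires strictly positive values.
#'
#' @param y Numeric trait vector.
#' @param transform `"identity"` or `"natural_log"`.
#' @return Transformed vector.
#' @seealso [back_transform()]
#' @export
transform_response <- function(y, transform = c("identity", "natural_log")) {
  transform <- match.arg(transform)
  if (transform == "identity") return(y)
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad))
    stop("natural_log transform needs positive values; offending sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  log(y)
}

#' Invert a trait response transform
#' @param y Transformed values.
#' @param transform `"identity"` or `"natural_log"`.
#' @return Values on the natural trait scale.
#' @export
back_transform <- function(y, transform = c("identity", "natural_log")) {
  transform <- match.arg(transform)
  if (transform == "identity") y else exp(y)
}

#' Validation metrics for a calibration model
#'
#' `rmsep` is the root mean square error of prediction,
#' `sqrt(mean((obs - pred)^2))`, in response units; `r_squared` is the
#' coefficient of determination of the predictions against the
#' observations, `1 - SS_res / SS_tot`. The squared Pearson correlation is
#' reported alongside as `r_pearson_sq` since some calibration literature
#' reports that quantity instead. When the model carries a response
#' transform, metrics are conventionally computed on the transformed scale.
#'
#' @param y_observed,y_predicted Numeric vectors of equal length >= 2.
#' @return A list of class `"metric_report"`: `r_squared`, `rmsep`,
#'   `n_validation`, `r_pearson_sq`.
#' @export
evaluate_model <- function(y_observed, y_predicted) {
  if (length(y_observed) != length(y_predicted))
    stop("observed and predicted lengths differ")
  if (length(y_observed) < 2) stop("need at least 2 values")
  rmsep <- sqrt(mean((y_observed - y_predicted)^2))
  ss_tot <- sum((y_observed - mean(y_observed))^2)
  if (ss_tot == 0)
    stop("r_squared undefined: zero observed variance (rmsep = ",
         format(rmsep), ")")
  r2 <- 1 - sum((y_observed - y_predicted)^2) / ss_tot
  rp <- if (stats::var(y_predicted) > 0)
    cor_pearson(y_observed, y_predicted)^2 else NA_real_
  structure(list(r_squared = r2, rmsep = rmsep,
                 n_validation = length(y_observed), r_pearson_sq = rp),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("R2 = %.3f, RMSEP = %.4g (n = %d)\n",
              x$r_squared, x$rmsep, x$n_validation))
  invisible(x)
}

#' F-statistic outlier screen on calibration residuals
#'
#' A univariate residual test: for each calibration sample the squared
#' residual is compared with the mean squared residual of all other
#' samples, `F_i = e_i^2 / s^2_(-i)` with
#' `s^2_(-i) = (SSE - e_i^2) / (n - 1)`, and flagged when it exceeds the
#' `percentile` quantile (default the 99.9th percentile) of the F
#' distribution with (1, n - 2) degrees of freedom. Flagged samples are
#' reported, never removed automatically: removal is an explicit reviewer
#' decision (see `remove_outliers` in [optimize_calibration()]), mirroring
#' the manual re-evaluation such screens require in practice.
#'
#' @param X Calibration predictor matrix the model was fit on.
#' @param y Calibration response (on the model's working scale).
#' @param model A `"plsr_model"` fit on `(X, y)`.
#' @param percentile F-distribution quantile level (default 0.999).
#' @return A data.frame of class `"outlier_report"` with one row per
#'   sample: `sample`, `residual`, `f_value`, `threshold`, `flagged`,
#'   `removed` (always `FALSE` here).
#' @export
detect_outliers <- function(X, y, model, percentile = 0.999) {
  if (length(y) < 5) stop("need at least 5 samples for the outlier screen")
  res <- y - predict(model, X)
  rep <- outlier_f_report(res, percentile)
  ids <- rownames(X)
  if (!is.null(ids)) rep$sample <- ids
  rep
}

# core of the screen, shared with direct residual-level use
outlier_f_report <- function(residuals, percentile = 0.999) {
  n <- length(residuals)
  sse <- sum(residuals^2)
  s2_loo <- (sse - residuals^2) / (n - 1)
  f <- ifelse(s2_loo > 0, residuals^2 / s2_loo,
              ifelse(residuals == 0, 0, Inf))
  thr <- stats::qf(percentile, 1, n - 2)
  structure(
    data.frame(sample = as.character(seq_len(n)),
               residual = residuals, f_value = f, threshold = thr,
               flagged = f > thr, removed = FALSE,
               stringsAsFactors = FALSE),
    class = c("outlier_report", "data.frame"))
}

#' Optimize a calibration model by randomized region search
#'
#' The full calibration procedure for one trait and one leaf state:
#'
#' 1. Match spectra (averaged, splice-corrected, one per sample in the
#'    requested `state`) to the reference trait values and apply the
#'    response transform.
#' 2. Draw a single Kennard-Stone 50/50 split on the full spectrum; the
#'    same split scores every iteration, so validation RMSEPs are
#'    comparable across region draws.
#' 3. Evaluate the full-spectrum model as a baseline, then `n_iterations`
#'    randomized region sets (up to `max_regions` intervals each). Each
#'    candidate chooses its component count by validation RMSEP
#'    ([choose_components()]), is fit on the calibration set, and is scored
#'    by validation RMSEP on the transformed scale.
#' 4. Keep the candidate with the lowest validation RMSEP (ties: higher
#'    R-squared, then the earlier iteration; the baseline counts as
#'    iteration 0, so region selection never returns a model worse than no
#'    selection).
#' 5. Screen the winner's calibration residuals with the F-statistic test;
#'    with `remove_outliers = TRUE` flagged samples are dropped and the
#'    winning configuration refit, otherwise they are only reported.
#'
#' @param s A [spectra_set()] (replicates are averaged and splices
#'   corrected automatically if not already done).
#' @param ref Reference table (see [read_reference()]).
#' @param trait `"leaf_N"` or `"leaf_P"`.
#' @param state Leaf state to calibrate on (`"fresh"`, `"dried"`, ...).
#' @param transform Response transform (default `"natural_log"` for leaf_N,
#'   `"identity"` for leaf_P when `NULL`).
#' @param n_iterations Number of randomized region draws (default 200);
#'   0 returns the full-spectrum baseline model.
#' @param max_regions,min_width Region-draw parameters (defaults 8 and
#'   20 nm).
#' @param split_fraction Kennard-Stone calibration fraction (default 0.5).
#' @param max_components Largest PLS component count considered (default
#'   10, capped by data size).
#' @param outlier_percentile F-quantile for the outlier screen (default
#'   0.999).
#' @param remove_outliers If `TRUE`, flagged samples are removed and the
#'   winner refit (default `FALSE`: report only).
#' @param seed Integer seed making the whole run reproducible.
#' @return An object of class `"calibration_model"`: the trait/state,
#'   winning `"region_set"`, transform, fitted `"plsr_model"`, the split,
#'   validation `"metric_report"`, the `"outlier_report"`, the per-
#'   iteration log (data.frame: iteration, n_regions, n_components, rmsep,
#'   r_squared), and provenance (seed, n_iterations, package version).
#' @export
optimize_calibration <- function(s, ref, trait = c("leaf_N", "leaf_P"),
                                 state = "dried", transform = NULL,
                                 n_iterations = 200, max_regions = 8,
                                 min_width = 20, split_fraction = 0.5,
                                 max_components = 10,
                                 outlier_percentile = 0.999,
                                 remove_outliers = FALSE, seed = 1) {
  trait <- match.arg(trait)
  if (is.null(transform))
    transform <- if (trait == "leaf_N") "natural_log" else "identity"
  transform <- match.arg(transform, c("identity", "natural_log"))
  stopifnot(inherits(s, "spectra_set"))
  ref <- validate_reference(ref)

  s <- subset_spectra(s, state = state)
  if (max(table(paste(s$meta$sample_id, s$meta$state))) > 1)
    s <- average_replicates(s)
  keep <- s$meta$sample_id %in% ref$sample_id
  if (sum(keep) < 8) stop("data-size error: fewer than 8 usable samples")
  s <- spectra_set(s$grid, s$meta[keep, , drop = FALSE],
                   s$values[keep, , drop = FALSE])
  y_nat <- ref[[trait]][match(s$meta$sample_id, ref$sample_id)]
  y <- transform_response(y_nat, transform)
  X_full <- s$values
  rownames(X_full) <- s$meta$sample_id

  set.seed(as.integer(seed) %% .Machine$integer.max)
  split <- kennard_stone_split(X_full, split_fraction)
  rows <- split_rows(split, X_full)

  evaluate_candidate <- function(regions) {
    Xr <- subset_by_regions(X_full, regions, grid = s$grid)
    k <- choose_components(Xr, y, max_components, split)
    fit <- fit_plsr(Xr[rows$calibration, , drop = FALSE],
                    y[rows$calibration], k)
    pred <- predict(fit, Xr[rows$validation, , drop = FALSE])
    met <- evaluate_model(y[rows$validation], pred)
    list(regions = regions, fit = fit, metrics = met, n_components = k)
  }

  candidates <- vector("list", n_iterations + 1L)
  candidates[[1]] <- evaluate_candidate(full_spectrum_regions(s$grid))
  if (n_iterations > 0) {
    for (i in seq_len(n_iterations)) {
      regions <- sample_region_set(s$grid, max_regions, min_width)
      candidates[[i + 1L]] <- evaluate_candidate(regions)
    }
  }
  log <- data.frame(
    iteration = seq_along(candidates) - 1L,
    n_regions = vapply(candidates, function(c.)
      nrow(unclass(c.$regions)), integer(1)),
    n_components = vapply(candidates, function(c.)
      as.integer(c.$n_components), integer(1)),
    rmsep = vapply(candidates, function(c.) c.$metrics$rmsep, numeric(1)),
    r_squared = vapply(candidates, function(c.) c.$metrics$r_squared,
                       numeric(1)))
  # lowest RMSEP; ties toward higher r_squared, then earlier iteration
  best <- order(log$rmsep, -log$r_squared, log$iteration)[1]
  winner <- candidates[[best]]

  Xw <- subset_by_regions(X_full, winner$regions, grid = s$grid)
  outliers <- detect_outliers(Xw[rows$calibration, , drop = FALSE],
                              y[rows$calibration], winner$fit,
                              outlier_percentile)
  if (remove_outliers && any(outliers$flagged)) {
    outliers$removed <- outliers$flagged
    keep_cal <- rows$calibration[!outliers$flagged]
    fit <- fit_plsr(Xw[keep_cal, , drop = FALSE], y[keep_cal],
                    min(winner$n_components, length(keep_cal) - 1L))
    pred <- predict(fit, Xw[rows$validation, , drop = FALSE])
    winner$fit <- fit
    winner$metrics <- evaluate_model(y[rows$validation], pred)
  }

  structure(
    list(trait = trait, state = state, regions = winner$regions,
         transform = transform, plsr = winner$fit, split = split,
         metrics = winner$metrics, n_components = winner$n_components,
         outliers = outliers, iteration_log = log,
         best_iteration = log$iteration[best],
         provenance = list(
           seed = as.integer(seed), n_iterations = as.integer(n_iterations),
           max_regions = max_regions, min_width = min_width,
           split_fraction = split_fraction,
           outlier_percentile = outlier_percentile,
           version = as.character(utils::packageVersion("leafnirs")))),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: %s / %s leaves, transform = %s\n",
              x$trait, x$state, x$transform))
  cat(sprintf("  %d region(s), %d PLS component(s); validation ",
              nrow(unclass(x$regions)), x$plsr$n_components))
  print(x$metrics)
  if (any(x$outliers$flagged))
    cat(sprintf("  %d calibration sample(s) flagged by the F screen\n",
                sum(x$outliers$flagged)))
  invisible(x)
}

#' Apply a calibration model to new spectra
#'
#' Averages replicates if needed, subsets the model's spectral regions,
#' predicts on the model's working scale, and back-transforms to natural
#' trait units.
#'
#' @param m A `"calibration_model"`.
#' @param s A [spectra_set()] on the same grid (caller is responsible for
#'   matching the preprocessing state: averaged, splice-corrected).
#' @return data.frame: `sample_id`, `state`, `group`, `predicted` (natural
#'   units), plus attributes `trait` and `model_state`.
#' @export
apply_model <- function(m, s) {
  stopifnot(inherits(m, "calibration_model"), inherits(s, "spectra_set"))
  if (max(table(paste(s$meta$sample_id, s$meta$state))) > 1)
    s <- average_replicates(s)
  Xr <- tryCatch(subset_by_regions(s, m$regions),
                 error = function(e) stop("shape error: grid mismatch (",
                                          conditionMessage(e), ")"))
  if (ncol(Xr) != length(m$plsr$x_mean))
    stop("shape error: grid mismatch between model and spectra")
  colnames(Xr) <- m$plsr$predictor_columns
  pred <- back_transform(predict(m$plsr, Xr), m$transform)
  out <- data.frame(sample_id = s$meta$sample_id, state = s$meta$state,
                    group = s$meta$group, predicted = pred,
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- m$trait
  attr(out, "model_state") <- m$state
  out
}

#' Save a calibration model as JSON
#'
#' All numeric arrays are stored as plain JSON lists at full double
#' precision, so save/load/apply round trips are bit-identical.
#'
#' @param m A `"calibration_model"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_calibration <- function(m, path) {
  doc <- list(
    schema = "leafnirs/calibration_model/1",
    trait = m$trait, state = m$state, transform = m$transform,
    regions = apply(unclass(m$regions), 1, function(r)
      list(start_nm = r[[1]], end_nm = r[[2]]), simplify = FALSE),
    plsr = list(
      n_components = m$plsr$n_components,
      x_mean = m$plsr$x_mean, y_mean = m$plsr$y_mean,
      x_sd = m$plsr$x_sd, scaled = m$plsr$scaled,
      x_weights = m$plsr$x_weights, x_loadings = m$plsr$x_loadings,
      y_loadings = m$plsr$y_loadings,
      regression_vector = m$plsr$regression_vector,
      predictor_columns = m$plsr$predictor_columns),
    split = list(fraction = m$split$fraction,
                 calibration_ids = m$split$calibration_ids,
                 validation_ids = m$split$validation_ids,
                 selection_order = m$split$selection_order),
    metrics = unclass(m$metrics),
    outliers = as.data.frame(m$outliers),
    best_iteration = m$best_iteration,
    provenance = m$provenance)
  # digits = I(17): 17 significant digits round-trip an IEEE double exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a calibration model saved by [save_calibration()]
#' @param path JSON path.
#' @return A `"calibration_model"` (without the iteration log, which is
#'   persisted separately as CSV).
#' @export
load_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "leafnirs/calibration_model/1"))
    stop("unrecognised calibration schema")
  p <- doc$plsr
  nc <- length(p$y_loadings)
  plsr <- structure(
    list(n_components = as.integer(p$n_components),
         x_mean = as.numeric(p$x_mean), y_mean = as.numeric(p$y_mean),
         x_sd = as.numeric(p$x_sd), scaled = isTRUE(p$scaled),
         x_weights = matrix(as.numeric(unlist(p$x_weights)), ncol = nc),
         x_loadings = matrix(as.numeric(unlist(p$x_loadings)), ncol = nc),
         y_loadings = as.numeric(p$y_loadings),
         regression_vector = as.numeric(p$regression_vector),
         predictor_columns = as.character(p$predictor_columns)),
    class = "plsr_model")
  regs <- structure(cbind(start_nm = doc$regions$start_nm,
                          end_nm = doc$regions$end_nm),
                    class = "region_set")
  structure(
    list(trait = doc$trait, state = doc$state, regions = regs,
         transform = doc$transform, plsr = plsr,
         split = structure(doc$split, class = "ks_split"),
         metrics = structure(doc$metrics, class = "metric_report"),
         n_components = as.integer(p$n_components),
         outliers = doc$outliers, iteration_log = NULL,
         best_iteration = doc$best_iteration,
         provenance = doc$provenance),
    class = "calibration_model")
}
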