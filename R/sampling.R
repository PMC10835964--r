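#' Kennard-Stone calibration/validation split
#'
#' Deterministic greedy max-min selection of a calibration subset that
#' spans spectral space; the remainder becomes the validation set. The
#' algorithm seeds with the two samples at maximum Euclidean distance, then
#' repeatedly adds the sample whose minimum distance to the already
#' selected set is largest, until `round(fraction * n)` (half-up) samples
#' are selected. All ties are broken toward the smaller original row index,
#' so the split is fully reproducible with no randomness.
#'
#' Distances are Euclidean on the rows of `X` as given (no autoscaling:
#' spectra share units). The split is typically drawn on the full
#' preprocessed spectrum, before any region subsetting, so that region-
#' search iterations are scored on a common validation set.
#'
#' @param X Numeric matrix, samples in rows; `rownames(X)` are used as
#'   sample identifiers (defaults to row indices).
#' @param fraction Proportion of samples selected into the calibration set,
#'   in (0, 1). Default 0.5 (a 50/50 split).
#' @return An object of class `"ks_split"`: list with `fraction`,
#'   `calibration_ids` (in selection order), `validation_ids`,
#'   `selection_order` (row indices of the calibration samples, in order),
#'   and `min_distances` (the max-min distance achieved at each step; the
#'   first entry is the seeding pair distance).
#' @export
kennard_stone_split <- function(X, fraction = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("configuration error: fraction must be in (0, 1)")
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  k <- floor(fraction * n + 0.5)  # round half-up
  k <- max(2L, as.integer(k))

  D <- as.matrix(stats::dist(X))
  if (max(D) == 0)
    stop("degenerate input: all rows identical (max pairwise distance 0)")

  # seed: lexicographically smallest (i, j) pair attaining the max distance
  m <- which(D == max(D), arr.ind = TRUE)
  m <- m[m[, 1] < m[, 2], , drop = FALSE]
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  sel <- c(m[1, 1], m[1, 2])
  min_d <- D[, sel[1]]
  min_d <- pmin(min_d, D[, sel[2]])
  achieved <- rep(max(D), 2)

  while (length(sel) < k) {
    cand_d <- min_d
    cand_d[sel] <- -Inf
    best <- which.max(cand_d)  # ties -> smallest index
    sel <- c(sel, best)
    achieved <- c(achieved, cand_d[best])
    min_d <- pmin(min_d, D[, best])
  }
  sel <- as.integer(sel)
  structure(
    list(fraction = fraction,
         calibration_ids = ids[sel],
         validation_ids = ids[setdiff(seq_len(n), sel)],
         selection_order = sel,
         min_distances = unname(achieved)),
    class = "ks_split"
  )
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("ks_split: %d calibration / %d validation (fraction %.2f)\n",
              length(x$calibration_ids), length(x$validation_ids),
              x$fraction))
  invisible(x)
}

#' Serialize a Kennard-Stone split to JSON
#' @param split A `"ks_split"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(
    list(fraction = split$fraction,
         calibration_ids = split$calibration_ids,
         validation_ids = split$validation_ids,
         selection_order = split$selection_order),
    path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}
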