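#' Spectral region set
#'
#' A set of wavelength intervals defining the predictor subset of a
#' calibration model. Intervals are snapped to the grid, sorted, and merged
#' when they overlap or share a boundary; each merged interval must be at
#' least `min_width` nm wide and the count must stay within `max_regions`.
#'
#' @param intervals Two-column matrix or list of `c(start_nm, end_nm)`
#'   pairs.
#' @param grid A [spectral_grid()].
#' @param max_regions Maximum number of merged intervals (default 8).
#' @param min_width Minimum interval width in nm (default 20).
#' @return An object of class `"region_set"`: matrix with columns
#'   `start_nm`, `end_nm`.
#' @export
region_set <- function(intervals, grid, max_regions = 8, min_width = 20) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  if (!nrow(intervals)) stop("configuration error: empty region set")
  if (any(intervals[, 1] > intervals[, 2])) stop("interval start > end")
  if (any(intervals[, 1] < grid$start_nm | intervals[, 2] > grid$end_nm))
    stop("intervals must lie within the grid bounds")
  o <- order(intervals[, 1], intervals[, 2])
  intervals <- intervals[o, , drop = FALSE]
  # merge overlapping or boundary-sharing intervals
  merged <- intervals[1, , drop = FALSE]
  for (i in seq_len(nrow(intervals))[-1]) {
    last <- nrow(merged)
    if (intervals[i, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], intervals[i, 2])
    } else {
      merged <- rbind(merged, intervals[i, , drop = FALSE])
    }
  }
  if (any(merged[, 2] - merged[, 1] < min_width))
    stop(sprintf("interval narrower than min_width = %g nm", min_width))
  if (nrow(merged) > max_regions)
    stop(sprintf("more than max_regions = %d intervals after merging",
                 max_regions))
  colnames(merged) <- c("start_nm", "end_nm")
  structure(merged, class = "region_set")
}

#' Full-spectrum region set
#' @param grid A [spectral_grid()].
#' @return A `"region_set"` spanning the whole grid.
#' @export
full_spectrum_regions <- function(grid) {
  region_set(matrix(c(grid$start_nm, grid$end_nm), 1), grid)
}

#' Draw a randomized region set
#'
#' One iteration of the randomized spectral-region search draws a region
#' count uniformly in `1..max_regions`, then that many intervals: each has
#' a width drawn uniformly on the grid between `min_width` and the span
#' divided by `max_regions` (so even the largest count can tile the
#' spectrum without forced overlap), and a uniformly drawn on-grid start.
#' Overlapping or touching draws are merged, so the realized count can be
#' smaller than the drawn one but always stays in `1..max_regions`. Uses
#' the current R random number generator state, so callers control
#' reproducibility with `set.seed()`.
#'
#' @param grid A [spectral_grid()].
#' @param max_regions Maximum region count per draw (default 8, as in the
#'   randomized search this package implements).
#' @param min_width Minimum interval width in nm (default 20).
#' @return A `"region_set"`.
#' @export
sample_region_set <- function(grid, max_regions = 8, min_width = 20) {
  if (max_regions < 1) stop("configuration error: max_regions must be >= 1")
  span <- grid$end_nm - grid$start_nm
  if (min_width > span)
    stop("configuration error: min_width exceeds the grid span")
  wl <- grid_wavelengths(grid)
  w_max <- max(min_width, span / max_regions)
  k <- sample.int(max_regions, 1)
  iv <- matrix(0, k, 2)
  for (i in seq_len(k)) {
    widths <- wl - grid$start_nm
    widths <- widths[widths >= min_width & widths <= w_max]
    w <- widths[sample.int(length(widths), 1)]
    starts <- wl[wl + w <= grid$end_nm]
    s <- starts[sample.int(length(starts), 1)]
    iv[i, ] <- c(s, s + w)
  }
  region_set(iv, grid, max_regions = max_regions, min_width = min_width)
}

#' Extract the predictor matrix for a region set
#'
#' Concatenates the grid columns inside each interval (closed intervals,
#' in wavelength order); shared boundaries never duplicate a column because
#' intervals are merged on construction. Column labels (wavelengths) are
#' retained.
#'
#' @param s A [spectra_set()] or a numeric matrix with wavelength column
#'   names on `grid`.
#' @param regions A `"region_set"`.
#' @param grid Required when `s` is a bare matrix.
#' @return Numeric matrix of the selected wavelength columns.
#' @export
subset_by_regions <- function(s, regions, grid = NULL) {
  if (inherits(s, "spectra_set")) {
    grid <- s$grid
    values <- s$values
  } else {
    if (is.null(grid)) stop("grid required for a bare matrix")
    values <- as.matrix(s)
  }
  wl <- grid_wavelengths(grid)
  keep <- rep(FALSE, length(wl))
  for (i in seq_len(nrow(unclass(regions)))) {
    keep <- keep | (wl >= regions[i, 1] & wl <= regions[i, 2])
  }
  if (!any(keep)) stop("configuration error: empty selection")
  values[, keep, drop = FALSE]
}
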