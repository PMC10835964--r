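#' Spectral grid
#'
#' Describes the wavelength axis shared by all spectra in a
#' [spectra_set()]: an arithmetic grid from `start_nm` to `end_nm` in steps
#' of `step_nm`, together with the detector splice points of the instrument.
#' The default grid (350--2500 nm, 1 nm step, 2151 points) matches a
#' full-range field spectroradiometer; the default splice points 1000 and
#' 1800 nm are the conventional boundaries between the VNIR and the two
#' SWIR detectors of such instruments and are configurable because
#' manufacturers do not standardise them.
#'
#' @param start_nm,end_nm First and last wavelength (nm).
#' @param step_nm Grid step (nm), must divide `end_nm - start_nm` exactly.
#' @param splice_points_nm Strictly increasing wavelengths strictly inside
#'   `(start_nm, end_nm)` marking detector boundaries; segments are the
#'   half-open runs between them.
#' @return An object of class `"spectral_grid"`.
#' @export
spectral_grid <- function(start_nm = 350, end_nm = 2500, step_nm = 1,
                          splice_points_nm = c(1000, 1800)) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (start_nm >= end_nm) stop("start_nm must be < end_nm")
  if (step_nm <= 0) stop("step_nm must be > 0")
  n <- (end_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-8)
    stop("step_nm must divide end_nm - start_nm exactly")
  sp <- as.numeric(splice_points_nm)
  if (length(sp)) {
    if (any(sp <= start_nm) || any(sp >= end_nm))
      stop("splice points must lie strictly inside (start_nm, end_nm)")
    if (is.unsorted(sp, strictly = TRUE))
      stop("splice points must be strictly increasing")
  }
  structure(
    list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm,
         splice_points_nm = sp),
    class = "spectral_grid"
  )
}

#' Wavelengths of a spectral grid
#' @param grid A [spectral_grid()].
#' @return Numeric vector of wavelengths (nm).
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  seq(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

grid_length <- function(grid) {
  as.integer(round((grid$end_nm - grid$start_nm) / grid$step_nm)) + 1L
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("spectral_grid: %g-%g nm, step %g nm (%d points), splices at %s\n",
              x$start_nm, x$end_nm, x$step_nm, grid_length(x),
              if (length(x$splice_points_nm))
                paste(x$splice_points_nm, collapse = ", ") else "none"))
  invisible(x)
}

VALID_STATES <- c("fresh", "dried", "treated", "rescanned")

#' Set of reflectance spectra on a common grid
#'
#' The central container of the package: a metadata table with one row per
#' scan (`sample_id`, `replicate`, `state`, optional `group`) aligned with a
#' numeric matrix of reflectances, one column per grid wavelength.
#' Reflectances must be finite and in (0, 1]; `(sample_id, replicate,
#' state)` must be unique.
#'
#' @param grid A [spectral_grid()].
#' @param meta data.frame with columns `sample_id` (character), `replicate`
#'   (integer >= 1), `state` (one of fresh/dried/treated/rescanned), and
#'   optionally `group` (character or NA).
#' @param values Numeric matrix, `nrow(meta)` rows by `grid` length columns.
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(grid, meta, values) {
  stopifnot(inherits(grid, "spectral_grid"), is.data.frame(meta),
            is.matrix(values))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "replicate", "state")
  if (!all(req %in% names(meta)))
    stop("meta must have columns sample_id, replicate, state")
  if (!"group" %in% names(meta)) meta$group <- NA_character_
  meta <- meta[, c("sample_id", "replicate", "state", "group")]
  meta$sample_id <- as.character(meta$sample_id)
  meta$replicate <- as.integer(meta$replicate)
  meta$state <- as.character(meta$state)
  meta$group <- as.character(meta$group)
  if (any(meta$replicate < 1L)) stop("replicate must be >= 1")
  bad_state <- setdiff(unique(meta$state), VALID_STATES)
  if (length(bad_state))
    stop("invalid state(s): ", paste(bad_state, collapse = ", "))
  if (nrow(values) != nrow(meta))
    stop("values must have one row per meta row")
  if (ncol(values) != grid_length(grid))
    stop(sprintf("grid mismatch: expected %d wavelength columns, got %d",
                 grid_length(grid), ncol(values)))
  key <- paste(meta$sample_id, meta$replicate, meta$state, sep = "\r")
  if (anyDuplicated(key))
    stop("(sample_id, replicate, state) must be unique")
  check_reflectance(values)
  colnames(values) <- format_wl(grid_wavelengths(grid))
  rownames(values) <- NULL
  rownames(meta) <- NULL
  structure(list(grid = grid, meta = meta, values = values),
            class = "spectra_set")
}

format_wl <- function(wl) {
  # integer-looking names where possible so wide CSV headers are clean
  ifelse(abs(wl - round(wl)) < 1e-9, format(round(wl), scientific = FALSE,
                                            trim = TRUE),
         format(wl, trim = TRUE))
}

check_reflectance <- function(values) {
  if (any(!is.finite(values)))
    stop("reflectance values must be finite; first offending row: ",
         which(!apply(is.finite(values), 1, all))[1])
  bad <- values <= 0 | values > 1
  if (any(bad)) {
    row <- which(apply(bad, 1, any))[1]
    stop(sprintf("reflectance outside (0,1] in row %d (value %g)",
                 row, values[row, which(bad[row, ])[1]]))
  }
  invisible(TRUE)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra (%d samples), states: %s\n",
              nrow(x$meta), length(unique(x$meta$sample_id)),
              paste(sort(unique(x$meta$state)), collapse = ", ")))
  print(x$grid)
  invisible(x)
}

#' Number of spectra in a set
#' @param s A [spectra_set()].
#' @return Integer count of spectra (rows).
#' @export
n_spectra <- function(s) nrow(s$meta)

#' Read spectra from CSV
#'
#' Two dialects are supported. `wide`: metadata columns `sample_id`,
#' `replicate`, `state`, `group` followed by one column per wavelength,
#' named by the wavelength in nm. `long`: columns `sample_id`, `replicate`,
#' `state`, `group`, `wavelength_nm`, `reflectance`. Wavelengths must form
#' an arithmetic grid; reflectances are validated into (0, 1].
#'
#' @param path CSV file path (UTF-8, "." decimal separator).
#' @param layout `"wide"` or `"long"`.
#' @param splice_points_nm Splice points to attach to the grid.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, layout = c("wide", "long"),
                         splice_points_nm = c(1000, 1800)) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    metacols <- intersect(c("sample_id", "replicate", "state", "group"),
                          names(df))
    if (!"sample_id" %in% metacols)
      stop("format error: wide layout needs a sample_id column")
    wlcols <- setdiff(names(df), metacols)
    wl <- suppressWarnings(as.numeric(wlcols))
    if (!length(wlcols) || any(is.na(wl)))
      stop("format error: missing or non-numeric wavelength columns")
    o <- order(wl)
    wl <- wl[o]
    values <- as.matrix(df[, wlcols[o], drop = FALSE])
    storage.mode(values) <- "double"
    meta <- df[, metacols, drop = FALSE]
    if (!"replicate" %in% names(meta)) meta$replicate <- 1L
    if (!"state" %in% names(meta)) meta$state <- "fresh"
  } else {
    req <- c("sample_id", "replicate", "state", "wavelength_nm",
             "reflectance")
    if (!all(req %in% names(df)))
      stop("format error: long layout needs columns ",
           paste(req, collapse = ", "))
    if (!"group" %in% names(df)) df$group <- NA_character_
    wl <- sort(unique(df$wavelength_nm))
    key <- paste(df$sample_id, df$replicate, df$state, sep = "\r")
    ids <- unique(key)
    if (length(ids) * length(wl) != nrow(df))
      stop("grid mismatch: ragged long table (not every spectrum covers ",
           "every wavelength)")
    df <- df[order(match(key, ids), df$wavelength_nm), ]
    values <- matrix(df$reflectance, nrow = length(ids), ncol = length(wl),
                     byrow = TRUE)
    first <- !duplicated(paste(df$sample_id, df$replicate, df$state,
                               sep = "\r"))
    meta <- df[first, c("sample_id", "replicate", "state", "group")]
  }
  step <- diff(wl)
  if (length(wl) < 2 || any(abs(step - step[1]) > 1e-8))
    stop("grid mismatch: wavelengths do not form an arithmetic grid")
  grid <- spectral_grid(wl[1], wl[length(wl)], step[1],
                        splice_points_nm = splice_points_nm)
  spectra_set(grid, meta, values)
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra()]; values are written at full double precision
#' so a read/write round trip preserves them exactly.
#'
#' @param s A [spectra_set()].
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(s, "spectra_set"))
  if (layout == "wide") {
    df <- cbind(s$meta, as.data.frame(s$values, check.names = FALSE))
  } else {
    wl <- grid_wavelengths(s$grid)
    df <- data.frame(
      sample_id = rep(s$meta$sample_id, each = length(wl)),
      replicate = rep(s$meta$replicate, each = length(wl)),
      state = rep(s$meta$state, each = length(wl)),
      group = rep(s$meta$group, each = length(wl)),
      wavelength_nm = rep(wl, times = nrow(s$meta)),
      reflectance = as.vector(t(s$values)),
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wet-lab reference table
#'
#' Expects header `sample_id,species,leaf_N,leaf_P,fert_N_level,fert_P_level`.
#' Leaf N is a mass fraction in % dry mass, leaf P in mg per g dry mass;
#' both must be strictly positive. Fertilization levels, when present, must
#' come from the factorial design sets (N: 5/20/100/200, P: 1/4/20/40
#' kg ha-1 yr-1).
#'
#' @param path CSV file path.
#' @return A validated data.frame keyed by unique `sample_id`.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_reference(df)
}

FERT_N_LEVELS <- c(5, 20, 100, 200)
FERT_P_LEVELS <- c(1, 4, 20, 40)

validate_reference <- function(df) {
  req <- c("sample_id", "leaf_N", "leaf_P")
  if (!all(req %in% names(df)))
    stop("reference table needs columns ", paste(req, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("sample_id must be unique")
  if (any(!is.finite(df$leaf_N)) || any(df$leaf_N <= 0))
    stop("leaf_N must be finite and > 0")
  if (any(!is.finite(df$leaf_P)) || any(df$leaf_P <= 0))
    stop("leaf_P must be finite and > 0")
  if ("fert_N_level" %in% names(df)) {
    ok <- is.na(df$fert_N_level) | df$fert_N_level %in% FERT_N_LEVELS
    if (!all(ok)) stop("fert_N_level must be one of 5, 20, 100, 200")
  }
  if ("fert_P_level" %in% names(df)) {
    ok <- is.na(df$fert_P_level) | df$fert_P_level %in% FERT_P_LEVELS
    if (!all(ok)) stop("fert_P_level must be one of 1, 4, 20, 40")
  }
  df
}

#' Write a reference table to CSV
#' @param ref data.frame as returned by [read_reference()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  utils::write.csv(ref, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average scan replicates
#'
#' Each leaf is scanned several times on the same spot; the replicate
#' spectra are averaged wavelength-wise before any modelling. Returns one
#' spectrum per `(sample_id, state)` with `replicate` set to 1. Idempotent.
#'
#' @param s A [spectra_set()].
#' @return A [spectra_set()] with one spectrum per (sample_id, state).
#' @export
average_replicates <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  key <- paste(s$meta$sample_id, s$meta$state, sep = "\r")
  idx <- match(key, unique(key))
  values <- rowsum(s$values, idx, reorder = TRUE)
  counts <- tabulate(idx)
  values <- values / counts
  first <- !duplicated(key)
  meta <- s$meta[first, , drop = FALSE]
  meta$replicate <- 1L
  spectra_set(s$grid, meta, unname(values))
}

#' Correct detector splice steps
#'
#' Full-range spectroradiometers concatenate the output of several internal
#' detectors; small radiometric mismatches leave artificial steps at the
#' detector boundaries. This applies an additive per-segment offset, using
#' the first segment as the anchor: after each splice point, the whole later
#' segment is shifted so its first value equals the last value of the
#' preceding (already corrected) segment. Corrections therefore compose
#' left to right, and within-segment differences are untouched.
#'
#' Offsets can push values outside (0, 1]; corrected values are clipped
#' into (1e-6, 1] so downstream log/absorbance transforms stay defined, and
#' a warning reports how many values were clipped.
#'
#' @param s A [spectra_set()] whose grid carries the splice points.
#' @param splice_points_nm Optional override of the grid's splice points;
#'   each must lie on the grid.
#' @return A splice-corrected [spectra_set()].
#' @export
splice_correct <- function(s, splice_points_nm = NULL) {
  stopifnot(inherits(s, "spectra_set"))
  sp <- if (is.null(splice_points_nm)) s$grid$splice_points_nm
        else as.numeric(splice_points_nm)
  if (!length(sp)) return(s)
  wl <- grid_wavelengths(s$grid)
  pos <- match(sp, wl)
  if (any(is.na(pos)))
    stop("configuration error: splice point off-grid: ",
         paste(sp[is.na(pos)], collapse = ", "))
  values <- s$values
  # segment k runs (pos[k-1], pos[k]]; offset so values[, pos+1] matches
  # values[, pos] of the corrected left segment
  for (p in sort(pos)) {
    offset <- values[, p + 1L] - values[, p]
    later <- (p + 1L):ncol(values)
    values[, later] <- values[, later] - offset
  }
  n_clip <- sum(values <= 0 | values > 1)
  if (n_clip > 0)
    warning(sprintf("splice_correct: %d value(s) clipped into (1e-6, 1]",
                    n_clip))
  values <- pmin(pmax(values, 1e-6), 1)
  out <- s
  out$values <- values
  out
}

#' Subset a spectra set by metadata
#'
#' Convenience filter on the metadata columns; keeps grid and alignment.
#'
#' @param s A [spectra_set()].
#' @param state,sample_id,group Optional values to keep.
#' @return A [spectra_set()].
#' @export
subset_spectra <- function(s, state = NULL, sample_id = NULL, group = NULL) {
  keep <- rep(TRUE, nrow(s$meta))
  if (!is.null(state)) keep <- keep & s$meta$state %in% state
  if (!is.null(sample_id)) keep <- keep & s$meta$sample_id %in% sample_id
  if (!is.null(group)) keep <- keep & s$meta$group %in% group
  if (!any(keep)) stop("no spectra match the filter")
  spectra_set(s$grid, s$meta[keep, , drop = FALSE],
              s$values[keep, , drop = FALSE])
}
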