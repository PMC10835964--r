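#' Fit a PLS1 regression model (NIPALS)
#'
#' Partial least squares regression with a single response, the modelling
#' engine behind every calibration in this package. Components are
#' extracted sequentially: the weight vector for each component is the
#' covariance direction between the deflated predictors and the response
#' (for a single response the NIPALS inner loop converges in one pass, so
#' the extraction is a closed-form sequence of matrix products and is fully
#' deterministic). Predictors and response are centred on their training
#' means; predictors are not autoscaled by default since reflectance shares
#' units across wavelengths.
#'
#' Extraction stops early, with a message, if the deflated predictor matrix
#' or the weight vector collapses below the rank tolerance (1e-10 on
#' residual norms); the model is then truncated to the achieved number of
#' components.
#'
#' @param X Numeric matrix, samples in rows, predictors (wavelengths) in
#'   columns; column names are retained as `predictor_columns`.
#' @param y Numeric response vector, one value per row of `X`.
#' @param n_components Number of latent components, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param scale If `TRUE`, autoscale predictors to unit variance (default
#'   `FALSE`).
#' @return An object of class `"plsr_model"` with the centring means, the
#'   per-component weights/loadings (`x_weights`, `x_loadings`,
#'   `y_loadings`), per-component score norms, and `regression_vector`, the
#'   coefficients on centred predictors for the full component count.
#' @export
fit_plsr <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("X and y must be row-aligned")
  if (n < 2) stop("need at least 2 samples")
  kmax <- min(n - 1L, p)
  if (n_components < 1 || n_components > kmax)
    stop(sprintf("n_components must be in [1, %d]", kmax))
  if (stats::var(y) == 0) stop("degenerate input: zero-variance response")

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  x_sd <- rep(1, p)
  if (scale) {
    x_sd <- apply(Xc, 2, stats::sd)
    x_sd[x_sd == 0] <- 1
    Xc <- sweep(Xc, 2, x_sd, "/")
  }
  yc <- y - y_mean

  tol <- 1e-10
  W <- matrix(0, p, n_components)   # x weights
  P <- matrix(0, p, n_components)   # x loadings
  q <- numeric(n_components)        # y loadings
  tt <- numeric(n_components)       # score sums of squares
  scores <- matrix(0, n, n_components)
  achieved <- 0L
  for (a in seq_len(n_components)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < tol || sqrt(sum(Xc^2)) < tol) {
      message(sprintf("fit_plsr: components truncated at %d (residual X ",
                      achieved), "collapsed below tolerance)")
      break
    }
    w <- w / wn
    t_ <- drop(Xc %*% w)
    t2 <- sum(t_^2)
    if (t2 < tol) {
      message(sprintf("fit_plsr: components truncated at %d", achieved))
      break
    }
    p_ <- drop(crossprod(Xc, t_)) / t2
    q_ <- sum(yc * t_) / t2
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q_ * t_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_; tt[a] <- t2
    scores[, a] <- t_
    achieved <- a
  }
  if (achieved == 0L) stop("degenerate input: no component extractable")
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  q <- q[seq_len(achieved)]
  scores <- scores[, seq_len(achieved), drop = FALSE]

  cols <- colnames(X)
  if (is.null(cols)) cols <- as.character(seq_len(p))
  m <- structure(
    list(n_components = achieved,
         x_mean = x_mean, y_mean = y_mean, x_sd = x_sd, scaled = scale,
         x_weights = W, x_loadings = P, y_loadings = q,
         scores = scores,
         regression_vector = plsr_coef(W, P, q, achieved),
         predictor_columns = cols),
    class = "plsr_model")
  m
}

# regression vector on centred (and possibly scaled) predictors for the
# first k components: B_k = W_k (P_k' W_k)^{-1} q_k
plsr_coef <- function(W, P, q, k) {
  Wk <- W[, seq_len(k), drop = FALSE]
  Pk <- P[, seq_len(k), drop = FALSE]
  R <- crossprod(Pk, Wk)  # upper triangular in exact arithmetic
  drop(Wk %*% backsolve(R, q[seq_len(k)], upper.tri = TRUE))
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("plsr_model: %d component(s), %d predictor(s)%s\n",
              x$n_components, length(x$x_mean),
              if (x$scaled) ", autoscaled" else ""))
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' Computes `y_mean + (X - x_mean) %*% regression_vector` (after unit-
#' variance scaling if the model was fit with it). `X` must carry the same
#' predictor columns the model was fit on.
#'
#' @param object A `"plsr_model"`.
#' @param X Numeric matrix with columns matching `object$predictor_columns`.
#' @param n_components Optionally predict with a truncated component count
#'   `<= object$n_components`.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, X, n_components = NULL, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$x_mean))
    stop("shape error: predictor count mismatch")
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), object$predictor_columns))
    stop("shape error: predictor columns do not match the model")
  b <- object$regression_vector
  if (!is.null(n_components)) {
    if (n_components < 1 || n_components > object$n_components)
      stop("n_components out of range")
    b <- plsr_coef(object$x_weights, object$x_loadings, object$y_loadings,
                   n_components)
  }
  Xc <- sweep(X, 2, object$x_mean)
  if (object$scaled) Xc <- sweep(Xc, 2, object$x_sd, "/")
  drop(Xc %*% b) + object$y_mean
}

#' Choose the PLS component count by validation RMSEP
#'
#' Fits the model on the calibration rows of `split` with the maximum
#' requested component count, then scores validation RMSEP for every
#' truncated count 1..max and returns the count minimising it. Near-ties
#' (within a relative tolerance of 1e-8) are resolved toward fewer
#' components, so flat RMSEP curves yield the parsimonious model.
#'
#' @param X Predictor matrix over all samples (calibration and validation
#'   rows, in the order `split` indexes them).
#' @param y Response vector aligned with `X`.
#' @param max_components Largest candidate component count (capped by data
#'   size).
#' @param split A `"ks_split"` from [kennard_stone_split()], indexing rows
#'   of `X` via its `selection_order`/ids.
#' @return The chosen component count (integer).
#' @export
choose_components <- function(X, y, max_components, split) {
  X <- as.matrix(X)
  cal <- split_rows(split, X)$calibration
  val <- split_rows(split, X)$validation
  kmax <- min(max_components, length(cal) - 1L, ncol(X))
  if (kmax < 1) stop("max_components out of bounds")
  fit <- fit_plsr(X[cal, , drop = FALSE], y[cal], kmax)
  kmax <- fit$n_components
  rmsep <- vapply(seq_len(kmax), function(k) {
    pred <- predict(fit, X[val, , drop = FALSE], n_components = k)
    sqrt(mean((y[val] - pred)^2))
  }, numeric(1))
  best <- min(rmsep)
  which(rmsep <= best + 1e-8 * max(best, 1e-300))[1]
}

# map split ids back to row indices of X (rownames if present, else the
# stored selection order / complement)
split_rows <- function(split, X) {
  ids <- rownames(X)
  if (!is.null(ids) && all(c(split$calibration_ids, split$validation_ids)
                           %in% ids)) {
    list(calibration = match(split$calibration_ids, ids),
         validation = match(split$validation_ids, ids))
  } else {
    n <- nrow(X)
    list(calibration = split$selection_order,
         validation = setdiff(seq_len(n), split$selection_order))
  }
}
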