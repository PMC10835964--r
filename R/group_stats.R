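#' Kruskal-Wallis rank sum test
#'
#' Nonparametric comparison of two or more groups, implemented from the
#' rank-sum definition. Mid-ranks are assigned over the pooled sample; the
#' statistic is
#' `H = 12 / (N (N + 1)) * sum_i n_i (Rbar_i - (N + 1) / 2)^2`,
#' divided by the tie-correction factor
#' `C = 1 - sum(t^3 - t) / (N^3 - N)` over tie-group sizes `t`. The p-value
#' uses the chi-square approximation with `k - 1` degrees of freedom
#' (adequate at the small group sizes typical of treatment comparisons); a
#' Monte Carlo permutation p-value is available for very small groups.
#'
#' @param x Numeric values, or a named list of group value vectors (then
#'   `g` is ignored).
#' @param g Group labels aligned with `x`.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for `p_method = "permutation"`.
#' @return A list of class `"kw_result"`: `h_statistic`, `df`, `p_value`,
#'   `tie_correction`, `n`, `method`.
#' @export
kruskal_wallis <- function(x, g = NULL, p_method = c("chisq", "permutation"),
                           n_perm = 10000) {
  p_method <- match.arg(p_method)
  gv <- pool_groups(x, g)
  x <- gv$x; g <- gv$g
  k <- nlevels(g)
  N <- length(x)
  if (N < 3) stop("need total n >= 3")

  h <- kw_statistic(x, g)
  p <- if (p_method == "chisq") {
    stats::pchisq(h$H, df = k - 1, lower.tail = FALSE)
  } else {
    ge <- replicate(n_perm, kw_statistic(x, sample(g))$H)
    (sum(ge >= h$H) + 1) / (n_perm + 1)
  }
  structure(list(h_statistic = h$H, df = k - 1L, p_value = p,
                 tie_correction = h$C, n = N, method = p_method),
            class = "kw_result")
}

kw_statistic <- function(x, g) {
  N <- length(x)
  r <- rank(x)  # mid-ranks
  rbar <- tapply(r, g, mean)
  n_i <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  t <- table(x)
  C <- 1 - sum(t^3 - t) / (N^3 - N)
  # all observations tied: H = 0/0 -> defined as 0
  H <- if (C == 0) 0 else H / C
  list(H = H, C = if (C == 0) 1 else C)
}

pool_groups <- function(x, g) {
  if (is.list(x)) {
    if (is.null(names(x))) names(x) <- paste0("g", seq_along(x))
    g <- rep(names(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  if (length(x) != length(g)) stop("x and g must be aligned")
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(tabulate(g) == 0)) stop("validation error: empty group")
  if (any(!is.finite(x))) stop("values must be finite")
  list(x = x, g = g)
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: X2 = %.2f, df = %d, p = %.3g (%s)\n",
              x$h_statistic, x$df, x$p_value, x$method))
  invisible(x)
}

#' Dunn's post-hoc test
#'
#' Pairwise follow-up to a significant Kruskal-Wallis test, from the
#' definition: for groups i, j with pooled mid-ranks,
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 -
#' sum(t^3 - t) / (12 (N - 1))) (1 / n_i + 1 / n_j))`,
#' with two-sided p-values from the standard normal, adjusted across all
#' unordered pairs (Holm by default).
#'
#' @inheritParams kruskal_wallis
#' @param adjustment Any method of [stats::p.adjust()] (default
#'   `"holm"`), or `"none"`.
#' @return A data.frame of class `"dunn_result"`, one row per unordered
#'   pair: `group1`, `group2`, `z_statistic`, `p_raw`, `p_adjusted`, with
#'   attribute `adjustment`.
#' @export
dunn_test <- function(x, g = NULL, adjustment = "holm") {
  gv <- pool_groups(x, g)
  x <- gv$x; g <- gv$g
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- tabulate(g)
  t <- table(x)
  s2 <- N * (N + 1) / 12 - sum(t^3 - t) / (12 * (N - 1))
  pairs <- utils::combn(nlevels(g), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(s2 * (1 / n_i[i] + 1 / n_i[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(group1 = levels(g)[pairs[1, ]],
                    group2 = levels(g)[pairs[2, ]],
                    z_statistic = z, p_raw = p_raw,
                    p_adjusted = stats::p.adjust(p_raw, method = adjustment),
                    stringsAsFactors = FALSE)
  attr(out, "adjustment") <- adjustment
  class(out) <- c("dunn_result", "data.frame")
  out
}

#' Pearson product-moment correlation
#'
#' Sample correlation from the definition (centered cross-products over
#' the product of standard deviations). Errors on constant input, where
#' the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: constant input")
  cor_pearson(x, y)
}

cor_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}
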