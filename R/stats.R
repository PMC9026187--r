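# Statistical toolkit: paired t-test, Pearson correlation with the
# t-transform p-value, and Benjamini-Hochberg FDR correction. Degenerate
# inputs (zero variance) are flagged explicitly instead of propagating NaN.

#' Two-sided paired t-test
#'
#' Tests the mean of `d = y - x` against zero; depends on the paired
#' differences only. A zero-variance difference vector gives a flagged
#' degenerate result (`statistic`/`p_value` `NA`, `degenerate = TRUE`).
#'
#' @param x,y paired numeric vectors of equal length, `n >= 2`.
#' @return a `test_result` list: `statistic`, `p_value`, `df`, `n`,
#'   `estimate` (mean difference), `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stopf("need n >= 2 pairs")
  d <- y - x
  s <- stats::sd(d)
  if (s == 0) {
    return(test_result(NA_real_, NA_real_, n - 1L, n, mean(d),
                       degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  test_result(t, 2 * stats::pt(-abs(t), n - 1L), n - 1L, n, mean(d))
}

#' Pearson correlation with two-sided p-value
#'
#' `r` with the p-value from the t-transform
#' `t = r * sqrt((n-2) / (1-r^2))` on `n - 2` degrees of freedom.
#' Constant input yields a flagged degenerate result.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return a `test_result` list with `estimate = r`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stopf("need n >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(test_result(NA_real_, NA_real_, n - 2L, n, NA_real_,
                       degenerate = TRUE))
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(test_result(Inf * sign(r), 0, n - 2L, n, r))
  t <- r * sqrt((n - 2) / (1 - r^2))
  test_result(t, 2 * stats::pt(-abs(t), n - 2L), n - 2L, n, r)
}

test_result <- function(statistic, p_value, df, n, estimate,
                        degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, df = df, n = n,
                 estimate = estimate, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  if (x$degenerate) cat("<test_result> degenerate (zero variance), n =",
                        x$n, "\n")
  else cat(sprintf("<test_result> stat = %.4g, df = %d, p = %.4g, estimate = %.4g\n",
                   x$statistic, x$df, x$p_value, x$estimate))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure at level `alpha`; adjusted p-values are monotone
#' non-decreasing in the raw p-value rank and invariant to input order.
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `reject` (logical mask, original order) and
#'   `p_adjusted`.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(pvals, method = "BH")
  list(reject = p_adj <= alpha, p_adjusted = p_adj)
}
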