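# Likelihood-ratio testing and multiple-testing thresholds.

#' Likelihood-ratio test
#'
#' Computes `2 * (lnL1 - lnL0)` (clipped at zero; small negative differences
#' up to `tolerance` are treated as optimizer noise) and the upper-tail
#' chi-squared p-value with `df` degrees of freedom. The default degrees of
#' freedom in model comparisons elsewhere in the package is the difference in
#' free-parameter counts, but `df` can be pinned (e.g. to 1) to mirror
#' published conventions.
#'
#' @param lnL0,lnL1 Log-likelihoods of the null and alternative model.
#' @param df Degrees of freedom, at least 1.
#' @param tolerance Allowed negative slack in `lnL1 - lnL0` before an error
#'   is raised.
#' @return A list with `statistic`, `df` and `p_value`.
#' @examples
#' lrt_from_stat(9.743, df = 1)$p_value # ~0.0018
#' @export
lrt <- function(lnL0, lnL1, df = 1, tolerance = 1e-4) {
  stopifnot(df >= 1)
  delta <- lnL1 - lnL0
  if (delta < -tolerance) {
    stop("alternative model has worse likelihood (lnL1 - lnL0 = ",
         format(delta), "); fits are inconsistent")
  }
  lrt_from_stat(max(0, 2 * delta), df)
}

#' @rdname lrt
#' @param statistic A likelihood-ratio statistic (non-negative).
#' @export
lrt_from_stat <- function(statistic, df = 1) {
  stopifnot(statistic >= 0, df >= 1)
  list(statistic = statistic, df = df,
       p_value = pchisq(statistic, df = df, lower.tail = FALSE))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests performed, at least 1.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 24) # 0.00208...; prints as 0.002 at 3 decimals
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}
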