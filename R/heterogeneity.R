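#' Recover a standard error from a reported 95% confidence interval
#'
#' For symmetric Wald intervals, `se = (ci_high - ci_low) / (2 * 1.96)`.
#' Useful for heterogeneity tests on published estimates where only point
#' estimate and CI are printed.
#'
#' @param ci_low,ci_high Interval bounds (any scale; the SE is returned on
#'   the same scale).
#' @return The standard error.
#' @examples
#' se_from_ci(1.00, 1.46)
#' @export
se_from_ci <- function(ci_low, ci_high) {
  if (any(ci_high <= ci_low)) {
    abort("Degenerate confidence interval: `ci_high` must exceed `ci_low`.")
  }
  (ci_high - ci_low) / (2 * qnorm(0.975))
}

#' Test heterogeneity between two effect estimates
#'
#' Two estimates \eqn{E_1} and \eqn{E_2} with standard errors
#' \eqn{SE_1, SE_2} differ by \eqn{d = E_1 - E_2} with
#' \eqn{SE_d = \sqrt{SE_1^2 + SE_2^2}}; a two-sided z-test on
#' \eqn{z = d / SE_d} gives the heterogeneity p-value. Comparisons are made
#' on whatever common scale the inputs share — conventionally the
#' percent-change scale, so `d` is in percentage points.
#'
#' @param e1,e2 Point estimates on a common scale.
#' @param se1,se2 Their standard errors. Alternatively supply
#'   `ci1`/`ci2` as length-2 intervals and SEs are recovered via
#'   [se_from_ci()].
#' @param ci1,ci2 Optional 95% CIs, used when `se1`/`se2` are missing.
#' @param labels Length-2 character vector naming the two estimates.
#'
#' @return A one-row tibble: `label_1`, `label_2`, `d`, `se_d`, `ci_low`,
#'   `ci_high` (95% CI of the difference), `z`, `p_value`.
#' @examples
#' # printed estimates: nighttime 1.23 (1.00, 1.46), daytime 0.34 (0.20, 0.49)
#' compare_estimates(1.23, 0.34, ci1 = c(1.00, 1.46), ci2 = c(0.20, 0.49))
#' @export
compare_estimates <- function(e1, e2, se1 = NULL, se2 = NULL,
                              ci1 = NULL, ci2 = NULL,
                              labels = c("estimate_1", "estimate_2")) {
  if (is.null(se1)) {
    if (is.null(ci1)) abort("Provide `se1` or `ci1`.")
    se1 <- se_from_ci(ci1[1], ci1[2])
  }
  if (is.null(se2)) {
    if (is.null(ci2)) abort("Provide `se2` or `ci2`.")
    se2 <- se_from_ci(ci2[1], ci2[2])
  }
  if (se1 <= 0 || se2 <= 0) abort("Standard errors must be positive.")
  d <- e1 - e2
  se_d <- sqrt(se1^2 + se2^2)
  z <- d / se_d
  q <- qnorm(0.975)
  tibble(
    label_1 = labels[1], label_2 = labels[2],
    d = d, se_d = se_d,
    ci_low = d - q * se_d, ci_high = d + q * se_d,
    z = z, p_value = 2 * pnorm(-abs(z))
  )
}

#' Bonferroni adjustment for a family of subgroup comparisons
#'
#' Multiplies each p-value by the family size `m` and caps at 1. The family
#' is conventionally the set of non-reference levels compared within one
#' subgroup dimension for one outcome and exposure; `m` is recorded in the
#' output so the family size used is always explicit.
#'
#' @param p_values Numeric vector of unadjusted p-values in `[0, 1]`.
#' @param m Family size (number of comparisons), >= 1. Defaults to
#'   `length(p_values)`.
#' @return A tibble with `p_value`, `p_bonferroni`, `m`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  if (m < 1) abort("`m` must be >= 1.")
  tibble(p_value = p_values, p_bonferroni = pmin(1, m * p_values), m = m)
}
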