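#' Binomial variance of an age-specific prevalence estimate
#'
#' The standard approximation for a proportion estimated from `n`
#' respondents: `Var(pi) = pi * (1 - pi) / n`. Used per single year of age
#' with the smoothed prevalence and the observed (unweighted) sample size.
#'
#' @param pi Prevalence in `[0, 1]` (vectorized).
#' @param n Sample size(s), `>= 1`.
#' @return Variance(s) of the estimated proportion.
#' @examples
#' prevalence_variance(0.5, 100)  # 0.0025
#' @export
prevalence_variance <- function(pi, n) {
  if (any(!is.finite(pi)) || any(pi < 0 | pi > 1)) {
    abort("`pi` must lie in [0, 1]", class = "hcal_invalid_argument")
  }
  if (any(!is.finite(n)) || any(n < 1)) {
    abort("`n` must be >= 1", class = "hcal_invalid_argument")
  }
  pi * (1 - pi) / n
}

#' Variance of a Sullivan-type healthy-life-years estimate
#'
#' Propagates independent per-age prevalence variances through the Sullivan
#' sum: `Var = (1 / radix^2) * sum_x L(x)^2 * Var(pi(x))`. The same formula
#' applies to HE (period person-years `L(x)`) and to HCAL (diagonal cohort
#' person-years `L_c(x)`); mortality rates are treated as fixed, since in
#' practice nearly all the uncertainty comes from the health survey.
#' Correlation between ages induced by smoothing is ignored (independent
#' ages approximation).
#'
#' @param person_years Per-age person-years `L(x)` (period) or `L_c(x)`
#'   (diagonal cohort).
#' @param radix The life-table radix the person-years are scaled to.
#' @param variances Per-age `Var(pi(x))`, same length as `person_years`.
#' @return The variance of HE or HCAL, in squared years.
#' @seealso [prevalence_variance()], [interval_estimate()]
#' @export
sullivan_variance <- function(person_years, radix, variances) {
  if (length(person_years) != length(variances)) {
    abort(sprintf("grids differ: %d person-year values vs %d variances",
                  length(person_years), length(variances)),
          class = "hcal_invalid_argument")
  }
  if (radix <= 0) {
    abort("`radix` must be > 0", class = "hcal_invalid_argument")
  }
  sum(person_years^2 * variances) / radix^2
}

#' Point estimate with approximate 95% confidence interval
#'
#' @param point Point estimate(s), in years.
#' @param se Standard error(s), `>= 0`.
#' @return A tibble with columns `estimate`, `se`, `lower95`, `upper95`
#'   (`estimate -/+ 1.96 * se`).
#' @export
interval_estimate <- function(point, se) {
  if (any(se < 0)) {
    abort("`se` must be >= 0", class = "hcal_invalid_argument")
  }
  tibble(
    estimate = point,
    se = se,
    lower95 = point - 1.96 * se,
    upper95 = point + 1.96 * se
  )
}
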