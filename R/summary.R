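#' Bundle the four indicators for one population-year
#'
#' Runs the whole pipeline for one reference year: builds the period life
#' table (LE), reconstructs the cross-sectional cohort survivorship (CAL),
#' and applies the same prevalence schedule to both sets of person-years
#' (HE and HCAL). If the prevalence carries per-age sample sizes `n`,
#' analytic standard errors and 95% confidence intervals for HE and HCAL
#' are included (see [sullivan_variance()]).
#'
#' Prevalence schedules estimated from surveys usually cover a sub-range of
#' ages (e.g. 16+). Ages outside the observed range are filled by
#' [extend_prevalence()] before the Sullivan sums; the default carries the
#' boundary values outward unchanged.
#'
#' @inheritParams period_lifetable
#' @param prevalence Data frame with columns `age`, `pi` and optionally `n`
#'   (per-age effective sample size for standard errors).
#' @param year Reference year `t` for the period table, the cohort
#'   survivorship and the prevalence.
#' @param population Free-text population label carried into the output.
#' @param extend How to extend prevalence to uncovered ages:
#'   `"constant"` (carry the nearest observed value, the default) or
#'   `"zero"` below the youngest observed age.
#' @return A one-row tibble of class `health_summary` with columns
#'   `population, year, sex, le, he, cal, hcal, ratio_he_le,
#'   ratio_hcal_cal` and, when sample sizes are available, `he_se, he_lo95,
#'   he_hi95, hcal_se, hcal_lo95, hcal_hi95`.
#' @examples
#' sc <- synthetic_scenario()
#' surf <- make_surface(sc, years = 1915:2015, omega = 100)
#' prev <- make_prevalence(sc, ages = 16:100)
#' health_summary(surf, prev, year = 2015, population = "synthetic")
#' @export
health_summary <- function(surface, prevalence, year,
                           population = NA_character_, radix = 1,
                           a0_rule = c("keyfitz", "constant"),
                           close_with_exposure = TRUE,
                           extend = c("constant", "zero")) {
  a0_rule <- match.arg(a0_rule)
  extend <- match.arg(extend)
  lt <- period_lifetable(surface, year, radix = radix, a0_rule = a0_rule,
                         close_with_exposure = close_with_exposure)
  cs <- cohort_survivorship(surface, year, a0_rule = a0_rule,
                            close_with_exposure = close_with_exposure)
  prev <- extend_prevalence(prevalence, ages = lt$age, method = extend)

  le <- rev(cumsum(rev(lt$Lx)))[1] / attr(lt, "radix")
  he <- sullivan_he(lt, prev)
  cal_t <- cal(cs)
  hcal <- sullivan_hcal(cs, prev)

  out <- tibble(
    population = population,
    year = year,
    sex = attr(surface, "sex"),
    le = le, he = he, cal = cal_t, hcal = hcal,
    ratio_he_le = he / le,
    ratio_hcal_cal = hcal / cal_t
  )
  if ("n" %in% names(prev) && all(prev$n >= 1)) {
    v <- prevalence_variance(prev$pi, prev$n)
    he_se <- sqrt(sullivan_variance(lt$Lx, attr(lt, "radix"), v))
    hcal_se <- sqrt(sullivan_variance(cs$Lx, attr(cs, "radix"), v))
    he_ci <- interval_estimate(he, he_se)
    hcal_ci <- interval_estimate(hcal, hcal_se)
    out$he_se <- he_se
    out$he_lo95 <- he_ci$lower95
    out$he_hi95 <- he_ci$upper95
    out$hcal_se <- hcal_se
    out$hcal_lo95 <- hcal_ci$lower95
    out$hcal_hi95 <- hcal_ci$upper95
  }
  structure(out, class = c("health_summary", class(tibble())))
}

#' Compare two health summaries
#'
#' Produces signed differences `a - b` between two [health_summary()] rows:
#' in years for LE, HE, CAL and HCAL, and in percentage points for the
#' healthy-share ratios HE/LE and HCAL/CAL. Two pairings are supported:
#' change over time within one population and sex, or the gender gap within
#' one population and year.
#'
#' @param summary_a,summary_b One-row [health_summary()] tibbles.
#' @param mode `"time_change"` (same population and sex, different years) or
#'   `"gender_gap"` (same population and year, different sexes).
#' @return A tibble with columns `measure`, `value_a`, `value_b`,
#'   `difference` and `units`.
#' @export
compare_summaries <- function(summary_a, summary_b,
                              mode = c("time_change", "gender_gap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(summary_a, "health_summary"),
            inherits(summary_b, "health_summary"))
  same <- function(field) identical(summary_a[[field]], summary_b[[field]])
  if (mode == "time_change") {
    if (!same("population") || !same("sex")) {
      abort("time_change compares the same population and sex across years",
            class = "hcal_invalid_argument")
    }
    if (same("year")) {
      abort("time_change needs two different years",
            class = "hcal_invalid_argument")
    }
  } else {
    if (!same("population") || !same("year")) {
      abort("gender_gap compares two sexes within one population and year",
            class = "hcal_invalid_argument")
    }
    if (same("sex")) {
      abort("gender_gap needs two different sexes",
            class = "hcal_invalid_argument")
    }
  }
  measures <- c("le", "he", "cal", "hcal")
  ratios <- c("ratio_he_le", "ratio_hcal_cal")
  tibble(
    measure = c(measures, ratios),
    value_a = unname(c(unlist(summary_a[measures]),
                       100 * unlist(summary_a[ratios]))),
    value_b = unname(c(unlist(summary_b[measures]),
                       100 * unlist(summary_b[ratios]))),
    units = c(rep("years", 4), rep("percentage points", 2))
  ) |>
    dplyr::mutate(difference = .data$value_a - .data$value_b)
}

#' @export
print.health_summary <- function(x, ...) {
  cat(sprintf(
    "<health_summary> %s %s (%s): LE %.2f | HE %.2f | CAL %.2f | HCAL %.2f\n",
    ifelse(is.na(x$population), "?", x$population), x$year,
    ifelse(is.na(x$sex), "?", x$sex), x$le, x$he, x$cal, x$hcal
  ))
  NextMethod()
}

#' Tidy a health summary into long form
#'
#' @param x A `health_summary`.
#' @param ... Unused.
#' @return A tibble with one row per measure.
#' @method tidy health_summary
#' @export
tidy.health_summary <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(
      cols = -dplyr::any_of(c("population", "year", "sex")),
      names_to = "measure", values_to = "value"
    )
}
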