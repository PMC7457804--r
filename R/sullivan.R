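#' Survival in good health: survivorship weighted by healthy proportions
#'
#' Combines a survivorship function with age-specific prevalence of poor
#' health: `curve(x) = p(x) * (1 - pi(x))`, the probability of being both
#' alive and healthy at age `x`. With the cross-sectional cohort
#' survivorship both factors refer to the same real cohorts, which is the
#' conceptual point of the HCAL indicator.
#'
#' @param survivorship Either a data frame with columns `age` and `p`
#'   (e.g. a [cohort_survivorship()]), or a `lifetable`, whose `lx / radix`
#'   is used.
#' @param prevalence A data frame with columns `age` and `pi` (proportion in
#'   poor health, in `[0, 1]`), e.g. from [tabulate_prevalence()] or
#'   [smooth_prevalence()]. Must cover exactly the same age grid; no
#'   interpolation is performed.
#' @return A tibble with columns `age`, `p`, `pi` and `healthy`
#'   (`= p * (1 - pi)`).
#' @examples
#' # one cohort: 80% survived to age 60, 30% of survivors limited
#' healthy_survival_curve(
#'   data.frame(age = 60, p = 0.8),
#'   data.frame(age = 60, pi = 0.3)
#' )$healthy  # 0.56
#' @export
healthy_survival_curve <- function(survivorship, prevalence) {
  sv <- as_survivorship_df(survivorship)
  pv <- check_prevalence(prevalence)
  check_same_grid(sv$age, pv$age)
  tibble(
    age = sv$age,
    p = sv$p,
    pi = pv$pi[match(sv$age, pv$age)],
    healthy = sv$p * (1 - pv$pi[match(sv$age, pv$age)])
  )
}

#' Health expectancy by the Sullivan method
#'
#' Apportions the period life table's person-years into healthy and
#' unhealthy using age-specific prevalence of poor health:
#' `HE = sum_x (1 - pi(x)) * L(x) / l(0)`. With `pi` identically zero this
#' reduces to period life expectancy.
#'
#' @param lt A `lifetable` from [period_lifetable()] (a cohort table works
#'   too, giving a cohort health expectancy).
#' @param prevalence Data frame with columns `age`, `pi` on the same age
#'   grid as the table.
#' @return HE in years.
#' @seealso [sullivan_hcal()], [health_summary()]
#' @export
sullivan_he <- function(lt, prevalence) {
  stopifnot(inherits(lt, "lifetable"))
  pv <- check_prevalence(prevalence)
  check_same_grid(lt$age, pv$age)
  sullivan_sum(lt$Lx, attr(lt, "radix"), pv$pi[match(lt$age, pv$age)])
}

#' Cross-sectional average length of healthy life
#'
#' The CAL-based Sullivan variant: the same prevalence schedule that feeds
#' [sullivan_he()] is applied to the diagonal (real-cohort) person-years of
#' the cross-sectional survivorship,
#' `HCAL = sum_x (1 - pi(x)) * L_c(x) / l_0^c`. Here the survivors and the
#' respondents reporting their health are the same cohorts, so mortality
#' and health information are conceptually aligned.
#'
#' @param cs A [cohort_survivorship()] for the reference year of the
#'   prevalence data.
#' @param prevalence Data frame with columns `age`, `pi` on the same grid.
#' @return HCAL in years.
#' @export
sullivan_hcal <- function(cs, prevalence) {
  stopifnot(inherits(cs, "cohort_survivorship"))
  pv <- check_prevalence(prevalence)
  check_same_grid(cs$age, pv$age)
  sullivan_sum(cs$Lx, attr(cs, "radix"), pv$pi[match(cs$age, pv$age)])
}

sullivan_sum <- function(Lx, radix, pi) {
  sum((1 - pi) * Lx) / radix
}

as_survivorship_df <- function(x) {
  if (inherits(x, "lifetable")) {
    return(tibble(age = x$age, p = x$lx / attr(x, "radix")))
  }
  x <- as_tibble(x)
  if (!all(c("age", "p") %in% names(x))) {
    abort("survivorship needs columns `age` and `p` (or pass a lifetable)",
          class = "hcal_invalid_argument")
  }
  x[c("age", "p")]
}

check_prevalence <- function(prevalence) {
  pv <- as_tibble(prevalence)
  if (!all(c("age", "pi") %in% names(pv))) {
    abort("prevalence needs columns `age` and `pi`",
          class = "hcal_invalid_argument")
  }
  if (anyNA(pv$pi) || any(pv$pi < 0 | pv$pi > 1)) {
    abort("prevalence `pi` must lie in [0, 1] with no missing values",
          class = "hcal_invalid_argument")
  }
  pv
}

check_same_grid <- function(ages_a, ages_b) {
  if (!identical(sort(as.numeric(ages_a)), sort(as.numeric(ages_b)))) {
    abort(sprintf(
      "age grids differ: %d-%d (n=%d) vs %d-%d (n=%d); align them explicitly",
      min(ages_a), max(ages_a), length(ages_a),
      min(ages_b), max(ages_b), length(ages_b)
    ), class = "hcal_invalid_argument")
  }
  invisible(TRUE)
}
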