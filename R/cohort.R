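#' Reconstruct the cross-sectional cohort survivorship for a reference year
#'
#' For a reference year `t`, the cohort aged `x` was born in `t - x`. Its
#' probability of having survived from birth to exact age `x` is obtained by
#' chaining the period death rates it was actually exposed to along its
#' Lexis diagonal:
#' `p_c(x) = prod_{a=0}^{x-1} (1 - q(a, t - x + a))`,
#' where each `q(a, y)` is converted from the rate in cell `(a, y)` of the
#' surface. Unlike a single cohort's survivorship, the resulting
#' cross-sectional function need not decrease monotonically in age: when a
#' cohort was exposed to harsher conditions than the cohort one year older
#' (e.g. a birth shock), `p_c(x)` rises at that age.
#'
#' Diagonal person-years `L_c(x)` are computed within each cohort's own
#' diagonal with the same separation-factor and terminal-closure rules as
#' [period_lifetable()], so that on a time-constant surface the
#' reconstruction reproduces the period table exactly.
#'
#' @inheritParams period_lifetable
#' @param reference_year The year `t` the cross-section refers to. The
#'   surface must cover years `t - omega(surface)` through `t` unless
#'   `allow_truncated` is set.
#' @param allow_truncated If `TRUE` and the surface does not reach back
#'   `omega` years, reconstruct only the ages with a complete diagonal and
#'   flag the result as truncated (its integral is then a truncated CAL, a
#'   different measure). Default `FALSE`: insufficient history is an error.
#' @return A tibble of class `cohort_survivorship` with columns `age`,
#'   `cohort` (birth year `t - x`), `p` (survivorship, `p(0) = 1`) and `Lx`
#'   (diagonal person-years, radix 1), plus attributes `reference_year` and
#'   `truncated`.
#' @seealso [cal()], [sullivan_hcal()]
#' @examples
#' surf <- make_surface(synthetic_scenario(), years = 1915:2015, omega = 100)
#' cs <- cohort_survivorship(surf, reference_year = 2015)
#' cal(cs)
#' @export
cohort_survivorship <- function(surface, reference_year,
                                a0_rule = c("keyfitz", "constant"),
                                close_with_exposure = TRUE,
                                allow_truncated = FALSE) {
  a0_rule <- match.arg(a0_rule)
  stopifnot(inherits(surface, "mortality_surface"))
  years <- surface_years(surface)
  om <- omega(surface)
  if (!reference_year %in% years) {
    abort(sprintf("reference year %d not covered by the surface (%d-%d)",
                  reference_year, min(years), max(years)),
          class = "hcal_missing_data")
  }
  depth <- reference_year - min(years)
  truncated <- depth < om
  if (truncated && !allow_truncated) {
    abort(sprintf(
      paste0("reconstructing ages 0-%d in %d requires rates back to %d, ",
             "but the surface starts in %d"),
      om, reference_year, reference_year - om, min(years)
    ), class = "hcal_missing_data")
  }
  om_eff <- min(om, depth)
  m <- surface_matrix(surface)
  ycol <- function(y) match(y, as.integer(colnames(m)))

  ages <- 0:om_eff
  p <- numeric(length(ages))
  Lx <- numeric(length(ages))
  t <- reference_year
  n_clamped <- 0L
  count_clamps <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("clamped", conditionMessage(w))) {
        hits <- suppressWarnings(
          as.integer(sub("^(\\d+) q.*", "\\1", conditionMessage(w))))
        n_clamped <<- n_clamped + ifelse(is.na(hits), 1L, hits)
        invokeRestart("muffleWarning")
      }
    })
  }
  for (x in ages) {
    # survival of the cohort born t - x from birth to age x
    px <- 1
    if (x > 0) {
      diag_years <- (t - x):(t - 1)
      mx_diag <- check_cells_present(m, 0:(x - 1), diag_years)
      ax_diag <- ax_schedule(mx_diag, a0_rule)
      qx_diag <- count_clamps(mx_to_qx(mx_diag, 1, ax_diag))
      for (i in seq_len(x)) px <- px * (1 - qx_diag[i])
    }
    p[x + 1] <- px
    # person-years lived between x and x+1 by this same cohort, which it
    # spends under the reference year's rates (cell (x, t))
    m_cont <- check_cells_present(m, x, t)
    if (x == om) {
      Lx[x + 1] <- if (close_with_exposure && m_cont > 0) px / m_cont else 0
    } else {
      a_cont <- if (x == 0) ax_schedule(m_cont, a0_rule)[1] else 0.5
      q_cont <- count_clamps(mx_to_qx(m_cont, 1, a_cont))
      p_next <- px * (1 - q_cont)
      Lx[x + 1] <- p_next + a_cont * (px - p_next)
    }
  }
  if (n_clamped > 0) {
    warn(sprintf("%d q(x) value(s) clamped to [0, 1] along the diagonals",
                 n_clamped))
  }
  structure(
    tibble(age = ages, cohort = t - ages, p = p, Lx = Lx),
    class = c("cohort_survivorship", class(tibble())),
    reference_year = t, radix = 1, truncated = truncated,
    a0_rule = a0_rule, close_with_exposure = close_with_exposure,
    sex = attr(surface, "sex")
  )
}

#' Cross-sectional average length of life
#'
#' CAL(t) integrates the cross-sectional cohort survivorship over age: the
#' sum of the diagonal person-years of all cohorts alive at `t`, standardized
#' to one newborn per cohort. It is a period measure built from the actual
#' mortality histories of the cohorts present in the population, and on a
#' time-constant surface it equals period life expectancy exactly.
#'
#' @param cs A [cohort_survivorship()].
#' @return CAL in years (a single number). For a truncated reconstruction
#'   the value is a truncated CAL over the available ages only, with a
#'   warning.
#' @examples
#' surf <- make_surface(synthetic_scenario(), years = 1915:2015, omega = 100)
#' cal(cohort_survivorship(surf, 2015))
#' @export
cal <- function(cs) {
  stopifnot(inherits(cs, "cohort_survivorship"))
  if (isTRUE(attr(cs, "truncated"))) {
    warn(sprintf("survivorship is truncated at age %d; value is a truncated CAL",
                 max(cs$age)))
  }
  # same accumulation order as the life table's T(x) so that the
  # stationarity identity CAL = e0 holds bit-for-bit
  rev(cumsum(rev(cs$Lx)))[1] / attr(cs, "radix")
}

#' @export
print.cohort_survivorship <- function(x, ...) {
  cat(sprintf("<cohort_survivorship> reference year %d, ages 0-%d%s\n",
              attr(x, "reference_year"), max(x$age),
              if (isTRUE(attr(x, "truncated"))) " (truncated)" else ""))
  NextMethod()
}

#' Summarize a cohort survivorship
#'
#' @param x A `cohort_survivorship`.
#' @param ... Unused.
#' @return One-row tibble with the reference year, CAL and truncation flag.
#' @method glance cohort_survivorship
#' @export
glance.cohort_survivorship <- function(x, ...) {
  tibble(
    reference_year = attr(x, "reference_year"),
    cal = suppressWarnings(cal(x)),
    omega = max(x$age),
    truncated = isTRUE(attr(x, "truncated"))
  )
}
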