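#' Plot a life table's survivorship
#'
#' @param object A `lifetable`.
#' @param ... Unused.
#' @return A ggplot of `l(x) / l(0)` against age.
#' @method autoplot lifetable
#' @export
autoplot.lifetable <- function(object, ...) {
  df <- tibble(age = object$age, p = object$lx / attr(object, "radix"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Age", y = "Survivorship l(x)/l(0)",
      title = sprintf("%s life table, %s (e0 = %.2f)",
                      attr(object, "type"), attr(object, "index_year"),
                      object$ex[1])
    ) +
    ggplot2::ylim(0, 1)
}

#' Plot a cross-sectional cohort survivorship
#'
#' The curve need not decrease monotonically: cohorts hit by harsher
#' conditions than their elders produce local rises.
#'
#' @param object A `cohort_survivorship`.
#' @param ... Unused.
#' @return A ggplot of `p_c(x)` against age.
#' @method autoplot cohort_survivorship
#' @export
autoplot.cohort_survivorship <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Age", y = "Cohort survivorship p_c(x)",
      title = sprintf("Cross-sectional cohort survivorship, %d (CAL = %.2f)",
                      attr(object, "reference_year"),
                      suppressWarnings(cal(object)))
    ) +
    ggplot2::ylim(0, 1)
}

#' Plot a smoothed prevalence schedule
#'
#' Raw weighted proportions as points, the penalized-spline fit as a line;
#' facetted by year when several years were smoothed.
#'
#' @param object A `prevalence_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prevalence_schedule
#' @export
autoplot.prevalence_schedule <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$pi_raw),
                        alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pi), linewidth = 0.8) +
    ggplot2::labs(x = "Age", y = "Prevalence of poor health") +
    ggplot2::ylim(0, 1)
  if ("year" %in% names(object) && length(unique(object$year)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$year))
  }
  p
}

#' Compare period and cross-sectional cohort survivorship
#'
#' Overlays `p(x, t)` from a period life table with `p_c(x, t - x)` from the
#' cohort reconstruction for the same reference year — the two survivorship
#' functions whose integrals are LE and CAL.
#'
#' @param lt A `lifetable` (period).
#' @param cs A `cohort_survivorship` for the same year.
#' @return A ggplot with both curves.
#' @export
plot_survivorship_comparison <- function(lt, cs) {
  stopifnot(inherits(lt, "lifetable"), inherits(cs, "cohort_survivorship"))
  df <- dplyr::bind_rows(
    tibble(age = lt$age, p = lt$lx / attr(lt, "radix"),
           curve = "period p(x,t)"),
    tibble(age = cs$age, p = cs$p, curve = "cohort p_c(x,t-x)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$p,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age", y = "Survivorship", colour = NULL) +
    ggplot2::ylim(0, 1)
}
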