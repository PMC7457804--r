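#' Convert a central death rate to a probability of dying
#'
#' Standard single-decrement conversion for an age interval of width `n`
#' with separation factor `a` (average person-years lived in the interval by
#' those dying in it): `q = n * m / (1 + (n - a) * m)`. Values that fall
#' outside `[0, 1]` (possible for very high raw rates at extreme ages) are
#' clamped to the boundary with a warning rather than an error.
#'
#' @param m Central death rate(s), deaths per person-year, `>= 0`.
#' @param n Width of the age interval in years (single-age tables use 1).
#' @param a Separation factor(s) in `(0, n]`; recycled against `m`.
#' @return Probability of dying within the interval, in `[0, 1]`.
#' @examples
#' mx_to_qx(0.1)            # 0.1 / 1.05
#' mx_to_qx(10)             # clamps to 1 with a warning
#' @export
mx_to_qx <- function(m, n = 1, a = 0.5) {
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("`m` must be finite and >= 0", class = "hcal_invalid_argument")
  }
  if (any(!is.finite(a)) || any(a <= 0) || any(a > n)) {
    abort("`a` must lie in (0, n]", class = "hcal_invalid_argument")
  }
  q <- n * m / (1 + (n - a) * m)
  out_of_range <- q > 1 | q < 0
  if (any(out_of_range)) {
    warn(sprintf("%d q(x) value(s) clamped to [0, 1]", sum(out_of_range)))
    q <- pmin(pmax(q, 0), 1)
  }
  q
}

# inverse of mx_to_qx, needed when chaining from published qx
qx_to_mx <- function(q, n = 1, a = 0.5) {
  q / (n - (n - a) * q)
}

# separation factors a(x): 0.5 everywhere except age 0
# keyfitz: a0 = 0.07 + 1.7 * m0, capped at 0.5
ax_schedule <- function(mx, a0_rule = c("keyfitz", "constant")) {
  a0_rule <- match.arg(a0_rule)
  ax <- rep(0.5, length(mx))
  ax[1] <- switch(a0_rule,
    keyfitz = min(0.5, 0.07 + 1.7 * mx[1]),
    constant = 0.3
  )
  ax
}

# Core single-age life-table arithmetic shared by the period table, the
# cohort table and the diagonal person-years of the cohort survivorship, so
# that stationarity identities hold bit-for-bit.
#
# lx is built by sequential multiplication (same as cumprod); L(x) =
# l(x+1) + a(x) * d(x). The terminal age is closed: q(omega) = 1 and
# L(omega) = l(omega) / m(omega) when close_with_exposure and m(omega) > 0,
# else 0.
lifetable_columns <- function(mx, ax, radix, close_with_exposure) {
  k <- length(mx)
  qx <- mx_to_qx(mx, 1, ax)
  qx[k] <- 1
  lx <- numeric(k)
  lx[1] <- radix
  for (i in seq_len(k - 1)) lx[i + 1] <- lx[i] * (1 - qx[i])
  lx_next <- c(lx[-1], 0)
  dx <- lx - lx_next
  Lx <- lx_next + ax * dx
  Lx[k] <- if (close_with_exposure && mx[k] > 0) lx[k] / mx[k] else 0
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  list(qx = qx, lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
}

new_lifetable <- function(mx, ages, radix, a0_rule, close_with_exposure,
                          type, index_year, sex) {
  ax <- ax_schedule(mx, a0_rule)
  cols <- lifetable_columns(mx, ax, radix, close_with_exposure)
  out <- tibble(
    age = ages, mx = mx, ax = ax, qx = cols$qx, lx = cols$lx,
    dx = cols$dx, Lx = cols$Lx, Tx = cols$Tx, ex = cols$ex
  )
  structure(
    out,
    class = c("lifetable", class(tibble())),
    radix = radix, type = type, index_year = index_year, sex = sex,
    a0_rule = a0_rule, close_with_exposure = close_with_exposure
  )
}

#' Build a period life table from a mortality surface
#'
#' Reads one calendar-year column of death rates off the surface and runs the
#' classic single-age life-table recursion mx -> qx -> lx -> Lx -> ex. The
#' resulting `e(0)` is period life expectancy: the mean lifetime of a
#' hypothetical cohort exposed at every age to that single year's rates.
#'
#' @param surface A [mortality_surface()].
#' @param year Calendar year to extract; must lie in the surface's range.
#' @param radix Number of newborns the table is standardized to (`l(0)`).
#'   Defaults to 1 so that `lx` is a survivorship probability; `e(0)` does
#'   not depend on it.
#' @param a0_rule Separation factor at age 0: `"keyfitz"`
#'   (`a0 = 0.07 + 1.7 m(0)`, capped at 0.5) or `"constant"` (0.3). All other
#'   ages use 0.5.
#' @param close_with_exposure How to close the open-ended terminal age
#'   `omega`: if `TRUE` (default) the terminal person-years are
#'   `l(omega) / m(omega)` (exponential exposure), if `FALSE` the table is
#'   truncated at `omega` (`L(omega) = 0`).
#' @return A tibble of class `lifetable` with columns `age, mx, ax, qx, lx,
#'   dx, Lx, Tx, ex` and attributes `radix`, `type`, `index_year`.
#' @seealso [cohort_lifetable()], [cohort_survivorship()]
#' @examples
#' surf <- make_surface(synthetic_scenario(), years = 2000:2010, omega = 100)
#' lt <- period_lifetable(surf, year = 2010)
#' life_expectancy(lt)
#' @export
period_lifetable <- function(surface, year, radix = 1,
                             a0_rule = c("keyfitz", "constant"),
                             close_with_exposure = TRUE) {
  a0_rule <- match.arg(a0_rule)
  stopifnot(inherits(surface, "mortality_surface"))
  years <- surface_years(surface)
  if (!year %in% years) {
    abort(sprintf("year %d not in surface range %d-%d", year,
                  min(years), max(years)),
          class = "hcal_missing_data")
  }
  m <- surface_matrix(surface)
  ages <- 0:omega(surface)
  mx <- check_cells_present(m, ages, rep(year, length(ages)))
  new_lifetable(mx, ages, radix, a0_rule, close_with_exposure,
                type = "period", index_year = year, sex = attr(surface, "sex"))
}

#' Build a real-cohort life table from a mortality surface
#'
#' Reads death rates along the Lexis diagonal of the cohort born in
#' `birth_year` — cell `(x, birth_year + x)` for each age `x` — and builds
#' the life table of that actual cohort. Requires the surface to cover years
#' `birth_year` through `birth_year + omega` (the extinct-cohort
#' requirement).
#'
#' @inheritParams period_lifetable
#' @param birth_year Birth year of the cohort.
#' @return A tibble of class `lifetable` (`type = "cohort"`).
#' @examples
#' surf <- make_surface(synthetic_scenario(), years = 1900:2005, omega = 100)
#' lt <- cohort_lifetable(surf, birth_year = 1900)
#' life_expectancy(lt)
#' @export
cohort_lifetable <- function(surface, birth_year, radix = 1,
                             a0_rule = c("keyfitz", "constant"),
                             close_with_exposure = TRUE) {
  a0_rule <- match.arg(a0_rule)
  stopifnot(inherits(surface, "mortality_surface"))
  ages <- 0:omega(surface)
  needed <- birth_year + ages
  years <- surface_years(surface)
  absent <- setdiff(needed, years)
  if (length(absent) > 0) {
    abort(sprintf(
      "cohort %d needs years %d-%d; missing: %s", birth_year,
      min(needed), max(needed), paste(absent, collapse = ", ")
    ), class = "hcal_missing_data")
  }
  m <- surface_matrix(surface)
  mx <- check_cells_present(m, ages, needed)
  new_lifetable(mx, ages, radix, a0_rule, close_with_exposure,
                type = "cohort", index_year = birth_year,
                sex = attr(surface, "sex"))
}

#' Life expectancy at a given age from a life table
#'
#' @param lt A `lifetable`.
#' @param age Exact age, default 0.
#' @return `e(age)` in years.
#' @export
life_expectancy <- function(lt, age = 0) {
  stopifnot(inherits(lt, "lifetable"))
  i <- match(age, lt$age)
  if (is.na(i)) {
    abort(sprintf("age %s not in the table", age), class = "hcal_invalid_argument")
  }
  lt$ex[i]
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("<lifetable> %s %s, radix %g, e0 = %.3f\n",
              attr(x, "type"), attr(x, "index_year"), attr(x, "radix"),
              x$ex[1]))
  NextMethod()
}

#' @rdname lifetable-tidiers
#' @method tidy lifetable
#' @export
tidy.lifetable <- function(x, ...) {
  as_tibble(x)
}

#' Summarize a life table
#'
#' `glance()` returns a one-row summary of a fitted life table: its type
#' (period or cohort), the calendar or birth year it indexes, life
#' expectancy at birth, the radix and the terminal age.
#'
#' @param x A `lifetable`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name lifetable-tidiers
#' @method glance lifetable
#' @export
glance.lifetable <- function(x, ...) {
  tibble(
    type = attr(x, "type"),
    index_year = attr(x, "index_year"),
    e0 = x$ex[1],
    radix = attr(x, "radix"),
    omega = max(x$age),
    a0_rule = attr(x, "a0_rule")
  )
}
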