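#' Mortality surface: age-by-year grid of death rates
#'
#' A mortality surface holds single-age, single-year central death rates
#' m(x, t) on a rectangular, contiguous age-by-calendar-year grid. It is the
#' raw material for every longevity measure in the package: period and cohort
#' life tables read columns or Lexis diagonals off it, and the
#' cross-sectional cohort survivorship chains its rates longitudinally.
#'
#' The surface is stored in long form (one row per `year` x `age` cell) so it
#' pipes through dplyr verbs naturally; operations that need the grid use an
#' internal matrix view. Missing rates are stored as `NA` and only become an
#' error when a computation actually needs the cell.
#'
#' @param data A data frame with columns `year`, `age` and `rate`
#'   (deaths per person-year). Ages must form a contiguous integer grid
#'   starting at 0; years must be contiguous; every year must carry the full
#'   age range. Rates must be non-negative or `NA`.
#' @param sex Free-text label for the sex the rates refer to.
#' @param source Free-text provenance label (e.g. a file name or
#'   "synthetic"). For spliced surfaces this may differ by year block; see
#'   [splice_surfaces()].
#'
#' @return A tibble of class `mortality_surface` with attributes `sex` and
#'   `provenance` (a tibble mapping each year to its source label).
#' @examples
#' surf <- mortality_surface(
#'   tidyr::expand_grid(year = 2000:2002, age = 0:4) |>
#'     dplyr::mutate(rate = 0.01 * (age + 1))
#' )
#' omega(surf)
#' @export
mortality_surface <- function(data, sex = NA_character_, source = NA_character_) {
  data <- as_tibble(data)
  required <- c("year", "age", "rate")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`data` must have columns year, age, rate; missing: ",
      paste(missing_cols, collapse = ", ")
    ), class = "hcal_invalid_argument")
  }
  data <- data[required]
  if (any(!is.finite(data$age)) || any(data$age != round(data$age))) {
    abort("ages must be integers", class = "hcal_invalid_argument")
  }
  if (any(!is.finite(data$year)) || any(data$year != round(data$year))) {
    abort("years must be integer calendar years", class = "hcal_invalid_argument")
  }
  bad_rate <- !is.na(data$rate) & (!is.finite(data$rate) | data$rate < 0)
  if (any(bad_rate)) {
    abort("rates must be finite and >= 0 (or NA for missing)",
          class = "hcal_invalid_argument")
  }
  data$age <- as.integer(data$age)
  data$year <- as.integer(data$year)
  ages <- sort(unique(data$age))
  years <- sort(unique(data$year))
  if (min(ages) != 0) {
    abort("age grid must start at 0", class = "hcal_invalid_argument")
  }
  if (!identical(ages, seq(min(ages), max(ages))) ||
      !identical(years, seq(min(years), max(years)))) {
    abort("age and year grids must be contiguous", class = "hcal_invalid_argument")
  }
  if (max(ages) < 1) {
    abort("surface needs a maximum age of at least 1", class = "hcal_invalid_argument")
  }
  if (nrow(data) != length(ages) * length(years) ||
      anyDuplicated(data[c("year", "age")]) > 0) {
    abort("grid must be rectangular: every year needs every age exactly once",
          class = "hcal_invalid_argument")
  }
  data <- dplyr::arrange(data, .data$year, .data$age)
  structure(
    data,
    class = c("mortality_surface", class(tibble())),
    sex = sex,
    provenance = tibble(year = years, source = source)
  )
}

#' @rdname mortality_surface
#' @param x A `mortality_surface`.
#' @export
omega <- function(x) max(x$age)

#' @rdname mortality_surface
#' @export
surface_years <- function(x) sort(unique(x$year))

# matrix view, ages in rows (0..omega), years in columns
surface_matrix <- function(surface) {
  ages <- 0:omega(surface)
  years <- surface_years(surface)
  m <- matrix(surface$rate, nrow = length(ages), ncol = length(years),
              dimnames = list(age = ages, year = years))
  m
}

# error if any needed cell is NA; cells given as data.frame(age, year)
check_cells_present <- function(m, ages, years) {
  idx <- cbind(ages + 1L, match(years, as.integer(colnames(m))))
  vals <- m[idx]
  if (anyNA(vals)) {
    bad <- which(is.na(vals))
    abort(paste0(
      "missing death rate at (age, year): ",
      paste0("(", ages[bad], ", ", years[bad], ")", collapse = ", ")
    ), class = "hcal_missing_data")
  }
  vals
}

#' @export
print.mortality_surface <- function(x, ...) {
  cat(sprintf(
    "<mortality_surface> ages 0-%d, years %d-%d, sex: %s\n",
    omega(x), min(x$year), max(x$year),
    ifelse(is.na(attr(x, "sex")), "?", attr(x, "sex"))
  ))
  NextMethod()
}
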