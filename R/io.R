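#' Read a Human Mortality Database Mx_1x1 rate file
#'
#' Parses the fixed HMD layout for single-age, single-year central death
#' rates: descriptive header lines, then a whitespace-separated table with
#' columns `Year, Age, Female, Male, Total`, the open age group written as
#' `"110+"` and missing cells as `"."`. One sex column is extracted into a
#' [mortality_surface()]; the open group is kept as the terminal age and
#' ages above `omega` are dropped, so `omega` becomes the surface's closed
#' maximum age. Missing cells become `NA` and only raise an error when a
#' computation needs them (e.g. the history check in
#' [cohort_survivorship()]).
#'
#' @param path Path to the file.
#' @param sex Which column to extract: `"male"`, `"female"` or `"total"`.
#' @param omega Maximum age to retain (default 100).
#' @return A [mortality_surface()].
#' @export
read_hmd_mx <- function(path, sex = c("male", "female", "total"),
                        omega = 100) {
  sex <- match.arg(sex)
  lines <- readLines(path)
  header_idx <- grep("^\\s*Year\\s+Age\\s+Female\\s+Male\\s+Total\\s*$", lines)
  if (length(header_idx) != 1) {
    abort(sprintf("no 'Year Age Female Male Total' header found in %s", path),
          class = "hcal_parse_error")
  }
  body <- lines[(header_idx + 1):length(lines)]
  body_lineno <- (header_idx + 1):length(lines)
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_lineno <- body_lineno[keep]
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) != 5)
  if (length(bad) > 0) {
    abort(sprintf("malformed row at line %d: expected 5 columns",
                  body_lineno[bad[1]]),
          class = "hcal_parse_error")
  }
  m <- do.call(rbind, fields)
  parse_num <- function(x, what, allow_missing = FALSE) {
    x2 <- x
    if (allow_missing) x2[x2 == "."] <- NA
    out <- suppressWarnings(as.numeric(x2))
    bad <- which(is.na(out) & (!allow_missing | x != "."))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric %s '%s' at line %d", what, x[bad[1]],
                    body_lineno[bad[1]]),
            class = "hcal_parse_error")
    }
    out
  }
  year <- parse_num(m[, 1], "Year")
  age_str <- sub("\\+$", "", m[, 2])
  age <- parse_num(age_str, "Age")
  col <- switch(sex, female = 3, male = 4, total = 5)
  rate <- parse_num(m[, col], paste0(sex, " rate"), allow_missing = TRUE)
  df <- tibble(year = year, age = age, rate = rate) |>
    dplyr::filter(.data$age <= omega)
  # complete the rectangular grid; ages absent from the file are missing
  full <- tidyr::expand_grid(
    year = seq(min(df$year), max(df$year)),
    age = 0:min(omega, max(df$age))
  )
  df <- dplyr::left_join(full, df, by = c("year", "age"))
  mortality_surface(df, sex = sex, source = basename(path))
}

#' Read and write long-form surface CSV
#'
#' The package's native interchange format for mortality surfaces is a
#' plain CSV with columns `year,age,rate` (one row per cell; empty `rate`
#' for missing). A written surface re-reads to an equal object.
#'
#' @param path File path.
#' @param sex,source Labels for the resulting surface (read).
#' @return `read_surface_csv()` returns a [mortality_surface()];
#'   `write_surface_csv()` returns `path` invisibly.
#' @export
read_surface_csv <- function(path, sex = NA_character_,
                             source = basename(path)) {
  df <- utils::read.csv(path, colClasses = c(NA, NA, "character"))
  if (!all(c("year", "age", "rate") %in% names(df))) {
    abort(sprintf("%s must have columns year,age,rate", path),
          class = "hcal_parse_error")
  }
  rate_chr <- df$rate
  rate_chr[rate_chr %in% c("", "NA", ".")] <- NA
  rate <- suppressWarnings(as.numeric(rate_chr))
  bad <- which(is.na(rate) & !is.na(rate_chr))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric rate '%s' at data row %d of %s",
                  rate_chr[bad[1]], bad[1], path),
          class = "hcal_parse_error")
  }
  mortality_surface(tibble(year = df$year, age = df$age, rate = rate),
                    sex = sex, source = source)
}

#' @rdname read_surface_csv
#' @param surface A [mortality_surface()] to write.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "mortality_surface"))
  utils::write.csv(as.data.frame(surface)[c("year", "age", "rate")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Splice two mortality surfaces at a cut year
#'
#' Joins a historical surface and a more recent one into a single
#' contiguous surface, taking years before `cut_year` from `older` and
#' years from `cut_year` onward from `newer` — the standard fix when one
#' national series does not reach far enough back (e.g. combining an
#' England-and-Wales series before 1922 with a UK series from 1922 on to
#' give the century of history a CAL reconstruction needs). Per-year
#' provenance labels of both inputs are retained.
#'
#' @param older,newer [mortality_surface()] objects with identical age
#'   grids. `older` must end in `cut_year - 1` and `newer` must start in
#'   `cut_year` (no gap, no ambiguous overlap).
#' @param cut_year First calendar year taken from `newer`.
#' @return A [mortality_surface()] covering both year ranges.
#' @export
splice_surfaces <- function(older, newer, cut_year) {
  stopifnot(inherits(older, "mortality_surface"),
            inherits(newer, "mortality_surface"))
  if (omega(older) != omega(newer)) {
    abort(sprintf("age grids differ: 0-%d vs 0-%d",
                  omega(older), omega(newer)),
          class = "hcal_invalid_argument")
  }
  if (max(older$year) != cut_year - 1 || min(newer$year) != cut_year) {
    abort(sprintf(
      "older must end in %d and newer must start in %d (got %d and %d)",
      cut_year - 1, cut_year, max(older$year), min(newer$year)
    ), class = "hcal_invalid_argument")
  }
  combined <- dplyr::bind_rows(
    as_tibble(older)[c("year", "age", "rate")],
    as_tibble(newer)[c("year", "age", "rate")]
  )
  out <- mortality_surface(combined, sex = attr(newer, "sex"))
  attr(out, "provenance") <- dplyr::bind_rows(
    attr(older, "provenance"), attr(newer, "provenance")
  )
  out
}

#' Read prevalence data from CSV
#'
#' Accepts either survey microdata (`age,year,unhealthy,weight`; one row per
#' respondent) or pre-tabulated counts (`age,year,n_unhealthy,n_total`).
#' The `year` column is optional in both layouts. The result feeds
#' [tabulate_prevalence()] (microdata) or [smooth_prevalence()] directly.
#'
#' @param path File path.
#' @return A tibble; attribute `layout` is `"microdata"` or `"tabulated"`.
#' @export
read_prevalence_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  if (all(c("age", "unhealthy") %in% names(df))) {
    layout <- "microdata"
  } else if (all(c("age", "n_unhealthy", "n_total") %in% names(df))) {
    layout <- "tabulated"
  } else {
    abort(sprintf(
      "%s: expected columns age,unhealthy[,weight] or age,n_unhealthy,n_total",
      path
    ), class = "hcal_parse_error")
  }
  structure(df, layout = layout)
}

#' Write health summaries to CSV or JSON
#'
#' Emits one flat record per population-year-sex with the four indicators,
#' the healthy-share ratios and any standard errors and confidence bounds.
#'
#' @param x A [health_summary()] (or several row-bound ones).
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_health_summary <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
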