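#' Tabulate weighted prevalence from survey microdata
#'
#' Collapses individual survey records (age, binary health state, sampling
#' weight) into an age-specific prevalence schedule:
#' `pi(x)` = weighted share of records in poor health at age `x`, with the
#' unweighted record count `N(x)` kept alongside for standard errors. Ages
#' inside `age_range` with no records are retained with `n = 0` and
#' `pi = NA` so that gaps are visible rather than silently dropped.
#'
#' @param sample Data frame with columns `age` (integer years), `unhealthy`
#'   (0/1 or logical) and optionally `weight` (positive; defaults to 1) and
#'   `year`. If `year` is present, tabulation is done per year.
#' @param age_range Optional length-2 integer vector; restricts and pads the
#'   output grid to `age_range[1]:age_range[2]`.
#' @return A tibble with columns (`year`,) `age`, `pi`, `n` and
#'   `n_unhealthy` (weighted proportions, unweighted counts).
#' @examples
#' tabulate_prevalence(data.frame(
#'   age = c(50, 50), unhealthy = c(1, 0), weight = c(2, 1)
#' ))  # pi = 2/3
#' @export
tabulate_prevalence <- function(sample, age_range = NULL) {
  sample <- as_tibble(sample)
  if (!all(c("age", "unhealthy") %in% names(sample))) {
    abort("sample needs columns `age` and `unhealthy`",
          class = "hcal_invalid_argument")
  }
  if (!"weight" %in% names(sample)) sample$weight <- 1
  if (any(sample$weight <= 0)) {
    abort("weights must be > 0", class = "hcal_invalid_argument")
  }
  if (!is.null(age_range)) {
    if (length(age_range) != 2 || age_range[1] > age_range[2]) {
      abort("`age_range` must be c(min, max) with min <= max",
            class = "hcal_invalid_argument")
    }
    sample <- dplyr::filter(sample, .data$age >= age_range[1],
                            .data$age <= age_range[2])
    if (nrow(sample) == 0) {
      abort("no records within `age_range`", class = "hcal_invalid_argument")
    }
  }
  by_year <- "year" %in% names(sample)
  grp <- if (by_year) c("year", "age") else "age"
  out <- sample |>
    dplyr::mutate(unhealthy = as.numeric(.data$unhealthy)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      pi = sum(.data$weight * .data$unhealthy) / sum(.data$weight),
      n = dplyr::n(),
      n_unhealthy = sum(.data$unhealthy),
      .groups = "drop"
    )
  if (!is.null(age_range)) {
    full <- if (by_year) {
      tidyr::expand_grid(year = sort(unique(out$year)),
                         age = age_range[1]:age_range[2])
    } else {
      tibble(age = age_range[1]:age_range[2])
    }
    out <- dplyr::left_join(full, out, by = grp) |>
      dplyr::mutate(
        n = dplyr::coalesce(.data$n, 0L),
        n_unhealthy = dplyr::coalesce(.data$n_unhealthy, 0)
      )
  }
  out
}

# Eilers-Marx B-spline basis on equally spaced knots
bspline_basis <- function(x, xl, xr, ndx, deg) {
  dx <- (xr - xl) / ndx
  knots <- seq(xl - deg * dx, xr + deg * dx, by = dx)
  splines::splineDesign(knots, x, ord = deg + 1, outer.ok = TRUE)
}

# second-order difference penalty, or a zero matrix when the basis is too
# small to carry it (then the smooth is saturated in that direction)
diff_penalty <- function(k, order) {
  if (k > order) {
    D <- diff(diag(k), differences = order)
    crossprod(D)
  } else {
    matrix(0, k, k)
  }
}

# Penalized IRLS for binomial counts c out of N with model matrix B and
# penalty matrix P (already scaled by lambda). Cells with N = 0 get zero
# weight. Returns coefficients, fitted probabilities, effective dimension
# and BIC.
pirls_binomial <- function(B, c_obs, N, P, eps = 1e-6,
                           maxit = 100, tol = 1e-8) {
  keep <- N > 0
  k <- ncol(B)
  p0 <- (c_obs + 0.5) / (N + 1)
  p0[!keep] <- mean(p0[keep])
  eta <- qlogis(pmin(pmax(p0, eps), 1 - eps))
  ridge <- diag(1e-8, k)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    p <- plogis(eta)
    w <- N * p * (1 - p)
    w[!keep] <- 0
    z <- eta + ifelse(keep, (c_obs - N * p) / pmax(w, 1e-12), 0)
    BtWB <- crossprod(B, w * B)
    A <- BtWB + P + ridge
    coef <- solve(A, crossprod(B, w * z))
    eta_new <- drop(B %*% coef)
    if (max(abs(eta_new - eta)) < tol) {
      eta <- eta_new
      converged <- TRUE
      break
    }
    eta <- eta_new
  }
  if (!converged) {
    abort(sprintf(
      "penalized binomial fit did not converge in %d iterations (max eta step %.3g)",
      maxit, max(abs(eta_new - eta))
    ), class = "hcal_convergence_error")
  }
  p <- plogis(eta)
  ed <- sum(diag(solve(A, BtWB)))
  mu <- N * p
  dev_terms <- ifelse(keep,
    2 * (ifelse(c_obs > 0, c_obs * log(c_obs / mu), 0) +
         ifelse(N - c_obs > 0, (N - c_obs) * log((N - c_obs) / (N - mu)), 0)),
    0)
  dev <- sum(dev_terms)
  list(coef = coef, fitted = pmin(pmax(p, eps), 1 - eps),
       ed = ed, deviance = dev,
       bic = dev + log(sum(keep)) * ed, iterations = iter)
}

default_lambda_grid <- function() 10^seq(-2, 4, length.out = 13)

#' Smooth age-specific prevalence with penalized B-splines
#'
#' Health prevalence tabulated by single year of age fluctuates strongly at
#' survey sample sizes. This smoother fits a penalized cubic B-spline model
#' to the binomial counts (unhealthy out of total per age, and optionally
#' per year): knots every `knot_spacing` ages, a difference penalty of order
#' `diff_order` on the coefficients, and the penalty weight chosen by a BIC
#' grid search unless fixed. The two-dimensional variant smooths over age
#' and calendar year jointly with separate penalties per dimension, for use
#' when a population has several consecutive survey years without breaks.
#'
#' The binomial likelihood is the exact model for proportions; for small
#' prevalence it coincides with the Poisson count smoothing often used for
#' mortality data.
#'
#' @param data Data frame with column `age` (and `year` for the 2D case) and
#'   either `n_unhealthy` + `n_total` (tabulated counts) or `pi` + `n` (as
#'   produced by [tabulate_prevalence()]). Ages with `n = 0` carry no
#'   information but may be present.
#' @param dimension `"age_1d"` smooths over age (independently per year if
#'   several years are present); `"age_year_2d"` smooths over age and year
#'   jointly.
#' @param penalty_selection `"bic"` (default) searches
#'   `lambda = 10^seq(-2, 4, length.out = 13)` per penalty and keeps the
#'   minimum-BIC fit; `"fixed"` uses `lambda` as given.
#' @param lambda Penalty weight(s) for `penalty_selection = "fixed"`: a
#'   single value for 1D, `c(age, year)` for 2D.
#' @param knot_spacing Distance between B-spline knots in years of age
#'   (and calendar years for the year dimension). Default 5.
#' @param degree B-spline degree, default 3 (cubic). The year basis degree
#'   is reduced when fewer years than `degree + 1` are available.
#' @param diff_order Order of the difference penalty, default 2.
#' @param eps Fitted probabilities are clipped to `[eps, 1 - eps]`.
#' @return A tibble of class `prevalence_schedule` with columns (`year`,)
#'   `age`, `pi_raw`, `pi` (smoothed), `n`, and a `smoothing` attribute
#'   (per-fit lambda, effective dimension, BIC, deviance). Use [glance()]
#'   to inspect it.
#' @examples
#' sc <- synthetic_scenario()
#' truth <- make_prevalence(sc, ages = 16:100)
#' svy <- draw_survey(truth, n_per_age = 500, seed = 1)
#' sm <- smooth_prevalence(tabulate_prevalence(svy))
#' glance(sm)
#' @export
smooth_prevalence <- function(data,
                              dimension = c("age_1d", "age_year_2d"),
                              penalty_selection = c("bic", "fixed"),
                              lambda = NULL,
                              knot_spacing = 5, degree = 3, diff_order = 2,
                              eps = 1e-6) {
  dimension <- match.arg(dimension)
  penalty_selection <- match.arg(penalty_selection)
  data <- as_tibble(data)
  if (all(c("n_unhealthy", "n_total") %in% names(data))) {
    data$.c <- data$n_unhealthy
    data$.N <- data$n_total
  } else if (all(c("pi", "n") %in% names(data))) {
    data$.c <- ifelse(data$n > 0, data$pi * data$n, 0)
    data$.N <- data$n
  } else {
    abort("data needs either n_unhealthy + n_total or pi + n columns",
          class = "hcal_invalid_argument")
  }
  if (any(data$.c > data$.N + 1e-8, na.rm = TRUE)) {
    abort("unhealthy counts exceed totals", class = "hcal_invalid_argument")
  }
  if (all(data$.N == 0)) {
    abort("all totals are zero; nothing to smooth",
          class = "hcal_invalid_argument")
  }
  if (penalty_selection == "fixed" && is.null(lambda)) {
    abort("`lambda` is required when penalty_selection = \"fixed\"",
          class = "hcal_invalid_argument")
  }

  if (dimension == "age_1d") {
    smooth_1d_by_year(data, penalty_selection, lambda, knot_spacing,
                      degree, diff_order, eps)
  } else {
    if (!"year" %in% names(data)) {
      abort("2D smoothing needs a `year` column",
            class = "hcal_invalid_argument")
    }
    smooth_2d(data, penalty_selection, lambda, knot_spacing,
              degree, diff_order, eps)
  }
}

smooth_1d_by_year <- function(data, penalty_selection, lambda, knot_spacing,
                              degree, diff_order, eps) {
  by_year <- "year" %in% names(data)
  groups <- if (by_year) split(data, data$year) else list(data)
  fits <- purrr::map(groups, function(d) {
    d <- dplyr::arrange(d, .data$age)
    ages <- d$age
    ndx <- max(1, ceiling((max(ages) - min(ages)) / knot_spacing))
    B <- bspline_basis(ages, min(ages), max(ages), ndx, degree)
    Pen <- diff_penalty(ncol(B), diff_order)
    grid <- if (penalty_selection == "bic") default_lambda_grid() else lambda[1]
    cand <- purrr::map(grid, function(lam) {
      pirls_binomial(B, d$.c, d$.N, lam * Pen, eps = eps)
    })
    best <- which.min(purrr::map_dbl(cand, "bic"))
    fit <- cand[[best]]
    out <- tibble(
      age = ages,
      pi_raw = ifelse(d$.N > 0, d$.c / d$.N, NA_real_),
      pi = fit$fitted,
      n = d$.N
    )
    if (by_year) out <- dplyr::mutate(out, year = d$year[1], .before = 1)
    meta <- tibble(
      year = if (by_year) d$year[1] else NA_integer_,
      lambda_age = grid[best], lambda_year = NA_real_,
      ed = fit$ed, bic = fit$bic, deviance = fit$deviance
    )
    list(out = out, meta = meta)
  })
  new_prevalence_schedule(
    dplyr::bind_rows(purrr::map(fits, "out")),
    dimension = "age_1d",
    smoothing = dplyr::bind_rows(purrr::map(fits, "meta")),
    penalty_selection = penalty_selection
  )
}

smooth_2d <- function(data, penalty_selection, lambda, knot_spacing,
                      degree, diff_order, eps) {
  data <- dplyr::arrange(data, .data$year, .data$age)
  ages <- sort(unique(data$age))
  years <- sort(unique(data$year))
  if (nrow(data) != length(ages) * length(years)) {
    abort("2D smoothing needs a complete age x year grid",
          class = "hcal_invalid_argument")
  }
  ndx_a <- max(1, ceiling((max(ages) - min(ages)) / knot_spacing))
  Ba <- bspline_basis(ages, min(ages), max(ages), ndx_a, degree)
  deg_y <- min(degree, length(years) - 1)
  ndx_y <- max(1, ceiling((max(years) - min(years)) / knot_spacing))
  By <- bspline_basis(years, min(years), max(years), ndx_y, deg_y)
  ka <- ncol(Ba)
  ky <- ncol(By)
  ai <- match(data$age, ages)
  yi <- match(data$year, years)
  # tensor-product rows, age index fastest
  B <- matrix(0, nrow(data), ka * ky)
  for (j in seq_len(ky)) {
    B[, (j - 1) * ka + seq_len(ka)] <- By[yi, j] * Ba[ai, ]
  }
  Pa <- kronecker(diag(ky), diff_penalty(ka, diff_order))
  Py <- kronecker(diff_penalty(ky, diff_order), diag(ka))

  grid <- if (penalty_selection == "bic") {
    tidyr::expand_grid(la = default_lambda_grid(), ly = default_lambda_grid())
  } else {
    if (length(lambda) != 2) {
      abort("2D fixed smoothing needs lambda = c(age, year)",
            class = "hcal_invalid_argument")
    }
    tibble(la = lambda[1], ly = lambda[2])
  }
  cand <- purrr::pmap(grid, function(la, ly) {
    pirls_binomial(B, data$.c, data$.N, la * Pa + ly * Py, eps = eps)
  })
  best <- which.min(purrr::map_dbl(cand, "bic"))
  fit <- cand[[best]]
  out <- tibble(
    year = data$year,
    age = data$age,
    pi_raw = ifelse(data$.N > 0, data$.c / data$.N, NA_real_),
    pi = fit$fitted,
    n = data$.N
  )
  new_prevalence_schedule(
    out,
    dimension = "age_year_2d",
    smoothing = tibble(
      year = NA_integer_,
      lambda_age = grid$la[best], lambda_year = grid$ly[best],
      ed = fit$ed, bic = fit$bic, deviance = fit$deviance
    ),
    penalty_selection = penalty_selection
  )
}

new_prevalence_schedule <- function(data, dimension, smoothing,
                                    penalty_selection) {
  structure(
    data,
    class = c("prevalence_schedule", class(tibble())),
    dimension = dimension,
    smoothing = smoothing,
    penalty_selection = penalty_selection
  )
}

#' Summarize a smoothed prevalence schedule
#'
#' @param x A `prevalence_schedule` from [smooth_prevalence()].
#' @param ... Unused.
#' @return A tibble with one row per fit: penalty weight(s), effective
#'   dimension, BIC and deviance.
#' @method glance prevalence_schedule
#' @export
glance.prevalence_schedule <- function(x, ...) {
  meta <- attr(x, "smoothing")
  meta$dimension <- attr(x, "dimension")
  meta
}

#' Extend a prevalence schedule to a full age grid
#'
#' Surveys observe health only over part of the life span (e.g. ages 16+),
#' while the Sullivan sums run over all life-table ages. This helper places
#' a schedule onto a target grid: ages below the youngest observed age are
#' filled with either the youngest observed value held constant (default)
#' or zero; ages above the oldest observed age always carry the oldest
#' value. Sample sizes are carried along with the values so that variance
#' propagation remains defined; extended rows are flagged.
#'
#' @param prevalence Data frame with columns `age`, `pi` and optionally `n`.
#' @param ages Integer vector, the target grid (e.g. `0:100`).
#' @param method Fill rule below the youngest observed age: `"constant"` or
#'   `"zero"`.
#' @return A tibble with columns `age`, `pi`, (`n`,) `extended`.
#' @export
extend_prevalence <- function(prevalence, ages,
                              method = c("constant", "zero")) {
  method <- match.arg(method)
  pv <- as_tibble(prevalence)
  if (!all(c("age", "pi") %in% names(pv))) {
    abort("prevalence needs columns `age` and `pi`",
          class = "hcal_invalid_argument")
  }
  pv <- dplyr::filter(pv, !is.na(.data$pi)) |> dplyr::arrange(.data$age)
  if (nrow(pv) == 0) {
    abort("no non-missing prevalence values to extend",
          class = "hcal_invalid_argument")
  }
  has_n <- "n" %in% names(pv)
  lo <- dplyr::first(pv)
  hi <- dplyr::last(pv)
  out <- tibble(age = as.integer(sort(ages)))
  idx <- match(out$age, pv$age)
  out$pi <- pv$pi[idx]
  if (has_n) out$n <- pv$n[idx]
  out$extended <- is.na(idx)
  below <- out$extended & out$age < lo$age
  above <- out$extended & out$age > hi$age
  inside <- out$extended & !below & !above
  if (any(inside)) {
    abort(paste0("schedule has gaps inside the observed range at ages: ",
                 paste(out$age[inside], collapse = ", ")),
          class = "hcal_invalid_argument")
  }
  out$pi[below] <- if (method == "constant") lo$pi else 0
  out$pi[above] <- hi$pi
  if (has_n) {
    out$n[below] <- lo$n
    out$n[above] <- hi$n
  }
  out
}
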