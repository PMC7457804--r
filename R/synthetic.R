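#' Synthetic scenario with known ground truth
#'
#' Defines a fully parametric world in which every quantity the package
#' estimates has a closed-form or directly computable truth: a
#' Gompertz-Makeham mortality surface with geometric secular improvement
#' (optionally disturbed by a birth-cohort shock), a logistic age profile
#' of limitation prevalence, and finite survey samples drawn from it.
#' Mortality is deterministic given the parameters — rates are treated as
#' fixed inputs, as is usual for vital-registration data — while all
#' sampling noise lives in the simulated surveys.
#'
#' The default parameters are the packaged "france_like" calibration: a
#' male-typical schedule chosen so that, with 2% annual mortality
#' improvement over the past century, period life expectancy at the
#' reference year is about 79 years and CAL about 74 years — the order of
#' magnitude seen in Western European male populations.
#'
#' @param makeham Background (age-independent) hazard `c >= 0`.
#' @param level Gompertz level `a > 0` (hazard at age 0 above background).
#' @param slope Gompertz slope `b > 0` (log-hazard increase per year of age).
#' @param improvement Annual improvement factor `rho` in `(0, 1]`; rates at
#'   calendar time `t` are multiplied by `rho^(t - anchor_year)`, so the
#'   past is worse for `rho < 1` and `rho = 1` gives a time-constant
#'   surface.
#' @param shock Optional birth-cohort mortality shock:
#'   `list(birth_year =, ages =, multiplier =)`. The rate in every Lexis
#'   cell `(x, birth_year + x)` with `x` in `ages` is multiplied by
#'   `multiplier`, producing the characteristic non-monotone bump in the
#'   cross-sectional survivorship.
#' @param prev_floor,prev_ceiling,prev_midpoint,prev_steepness Parameters of
#'   the logistic limitation-prevalence curve
#'   `pi(x) = floor + (ceiling - floor) / (1 + exp(-steepness (x - midpoint)))`.
#' @param n_per_age Default number of survey respondents per single year of
#'   age for [draw_survey()].
#' @return A list of class `synthetic_scenario`.
#' @examples
#' sc <- synthetic_scenario(improvement = 1)  # stationary world
#' surf <- make_surface(sc, years = 2000:2005, omega = 100)
#' @export
synthetic_scenario <- function(makeham = 1e-3,
                               level = 1.5e-5,
                               slope = 0.10,
                               improvement = 0.98,
                               shock = NULL,
                               prev_floor = 0.05,
                               prev_ceiling = 0.60,
                               prev_midpoint = 60,
                               prev_steepness = 0.10,
                               n_per_age = 500) {
  stopifnot(makeham >= 0, level > 0, slope > 0,
            improvement > 0, improvement <= 1,
            prev_floor >= 0, prev_ceiling <= 1, prev_floor <= prev_ceiling,
            n_per_age >= 1)
  if (!is.null(shock)) {
    stopifnot(is.list(shock),
              all(c("birth_year", "ages", "multiplier") %in% names(shock)),
              shock$multiplier >= 0)
  }
  structure(
    list(makeham = makeham, level = level, slope = slope,
         improvement = improvement, shock = shock,
         prev_floor = prev_floor, prev_ceiling = prev_ceiling,
         prev_midpoint = prev_midpoint, prev_steepness = prev_steepness,
         n_per_age = n_per_age),
    class = "synthetic_scenario"
  )
}

#' @rdname synthetic_scenario
#' @export
scenario_france_like <- function() synthetic_scenario()

#' Generate a mortality surface from a scenario
#'
#' Evaluates
#' `rate(x, t) = (c + a exp(b x)) * rho^(t - anchor_year)` on the requested
#' grid and applies the cohort shock multiplier along its Lexis diagonals.
#' Deterministic given the scenario.
#'
#' @param scenario A [synthetic_scenario()].
#' @param years Contiguous calendar years to generate.
#' @param omega Maximum age of the grid (default 100).
#' @param anchor_year Year at which the improvement factor equals 1;
#'   defaults to `max(years)`, so that the last year carries the scenario's
#'   base rates and earlier years are scaled up by `rho^-(gap)`.
#' @return A [mortality_surface()].
#' @export
make_surface <- function(scenario, years, omega = 100,
                         anchor_year = max(years)) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  grid <- tidyr::expand_grid(year = as.integer(years), age = 0:omega)
  grid$rate <- with(scenario,
    (makeham + level * exp(slope * grid$age)) *
      improvement^(grid$year - anchor_year))
  if (!is.null(scenario$shock)) {
    hit <- (grid$year - grid$age) == scenario$shock$birth_year &
      grid$age %in% scenario$shock$ages
    grid$rate[hit] <- grid$rate[hit] * scenario$shock$multiplier
  }
  mortality_surface(grid, sex = "synthetic", source = "synthetic")
}

#' True prevalence curve of a scenario
#'
#' @param scenario A [synthetic_scenario()].
#' @param ages Integer ages to evaluate.
#' @return A tibble with columns `age` and `pi` (the logistic truth).
#' @export
make_prevalence <- function(scenario, ages) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  pi <- with(scenario,
    prev_floor + (prev_ceiling - prev_floor) /
      (1 + exp(-prev_steepness * (ages - prev_midpoint))))
  tibble(age = as.integer(ages), pi = pi)
}

#' Draw a survey sample from a true prevalence curve
#'
#' For each age, draws `n_per_age` Bernoulli health states with the true
#' prevalence as success probability, optionally with lognormal sampling
#' weights. Reproducible under a fixed `seed` (the caller's RNG state is
#' restored afterwards).
#'
#' @param prevalence Data frame with columns `age` and `pi` (the truth),
#'   e.g. from [make_prevalence()].
#' @param n_per_age Respondents per age (scalar or per-age vector).
#' @param weights `"equal"` (all 1) or `"lognormal"` (meanlog 0, sdlog 0.5).
#' @param seed Optional integer seed.
#' @param year Optional survey year label added as a column.
#' @return A tibble with columns (`year`,) `age`, `unhealthy` (0/1),
#'   `weight` — one row per respondent.
#' @export
draw_survey <- function(prevalence, n_per_age = NULL,
                        weights = c("equal", "lognormal"),
                        seed = NULL, year = NULL) {
  weights <- match.arg(weights)
  pv <- check_prevalence(prevalence)
  if (is.null(n_per_age)) n_per_age <- 500
  n_per_age <- rep_len(n_per_age, nrow(pv))
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  total <- sum(n_per_age)
  out <- tibble(
    age = rep(pv$age, n_per_age),
    unhealthy = rbinom(total, 1, rep(pv$pi, n_per_age)),
    weight = if (weights == "lognormal") rlnorm(total, 0, 0.5) else rep(1, total)
  )
  if (!is.null(year)) out <- dplyr::mutate(out, year = year, .before = 1)
  out
}
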