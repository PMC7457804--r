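test_that("weighted tabulation matches hand computation and weight invariances", {
  out <- tabulate_prevalence(data.frame(
    age = c(50, 50), unhealthy = c(1, 0), weight = c(2, 1)
  ))
  expect_equal(out$pi, 2 / 3)
  expect_equal(out$n, 2L)

  healthy <- data.frame(age = rep(20:22, each = 4), unhealthy = 0)
  tab <- tabulate_prevalence(healthy)
  expect_true(all(tab$pi == 0))

  set.seed(7)
  mixed <- data.frame(age = rep(30, 50), unhealthy = rbinom(50, 1, 0.4))
  expect_equal(tabulate_prevalence(mixed)$pi, mean(mixed$unhealthy))
})

test_that("ages without records are padded as missing, empty ranges rejected", {
  out <- tabulate_prevalence(
    data.frame(age = c(20, 22), unhealthy = c(1, 0)),
    age_range = c(20, 23)
  )
  expect_equal(out$age, 20:23)
  expect_equal(out$n, c(1L, 0L, 1L, 0L))
  expect_true(is.na(out$pi[2]))
  expect_error(
    tabulate_prevalence(data.frame(age = 10, unhealthy = 1),
                        age_range = c(20, 30)),
    class = "hcal_invalid_argument"
  )
  expect_error(
    tabulate_prevalence(data.frame(age = 10, unhealthy = 1, weight = -1)),
    class = "hcal_invalid_argument"
  )
})

test_that("smoother recovers a constant prevalence with large samples", {
  ages <- 16:90
  counts <- data.frame(
    age = ages,
    n_unhealthy = round(0.3 * 1e5),
    n_total = 1e5
  )
  fit <- smooth_prevalence(counts)
  expect_true(all(abs(fit$pi - 0.3) < 0.01))
})

test_that("infinite penalty drives the 1D fit to a straight line on the logit scale", {
  set.seed(11)
  ages <- 16:90
  truth <- plogis(-4 + 0.05 * ages)
  counts <- data.frame(
    age = ages,
    n_unhealthy = rbinom(length(ages), 200, truth),
    n_total = 200
  )
  fit <- smooth_prevalence(counts, penalty_selection = "fixed", lambda = 1e9)
  eta <- qlogis(fit$pi)
  expect_lt(max(abs(diff(eta, differences = 2))), 1e-4)
})

test_that("smoothing noiseless smooth data is nearly idempotent", {
  sc <- synthetic_scenario()
  truth <- make_prevalence(sc, ages = 16:95)
  counts <- data.frame(
    age = truth$age,
    n_unhealthy = truth$pi * 1e6,  # noise-free expected counts
    n_total = 1e6
  )
  fit <- smooth_prevalence(counts)
  expect_true(all(abs(fit$pi - truth$pi) < 0.005))
})

test_that("2D fit separates into per-year 1D fits on a 2-year toy grid", {
  set.seed(21)
  ages <- 40:70
  d <- tidyr::expand_grid(year = 2008:2009, age = ages) |>
    dplyr::mutate(
      n_total = 300,
      n_unhealthy = rbinom(dplyr::n(), 300,
                           plogis(-5 + 0.06 * age + 0.2 * (year - 2008)))
    )
  two_d <- smooth_prevalence(d, dimension = "age_year_2d",
                             penalty_selection = "fixed", lambda = c(10, 1e8))
  per_year <- lapply(split(d, d$year), function(dd) {
    smooth_prevalence(dd[c("age", "n_unhealthy", "n_total")],
                      penalty_selection = "fixed", lambda = 10)
  })
  expect_equal(two_d$pi[two_d$year == 2008], per_year[["2008"]]$pi,
               tolerance = 1e-6)
  expect_equal(two_d$pi[two_d$year == 2009], per_year[["2009"]]$pi,
               tolerance = 1e-6)
})

test_that("2D BIC fit returns one joint schedule with fitted values in (0,1)", {
  set.seed(31)
  d <- tidyr::expand_grid(year = 2008:2014, age = 16:90) |>
    dplyr::mutate(
      n_total = 120,
      n_unhealthy = rbinom(dplyr::n(), 120,
                           plogis(-4.5 + 0.05 * age - 0.02 * (year - 2008)))
    )
  fit <- smooth_prevalence(d, dimension = "age_year_2d")
  expect_equal(nrow(fit), nrow(d))
  expect_true(all(fit$pi > 0 & fit$pi < 1))
  g <- glance(fit)
  expect_true(is.finite(g$lambda_year))
  expect_gt(g$ed, 1)
})

test_that("degenerate inputs are rejected", {
  expect_error(
    smooth_prevalence(data.frame(age = 1:5, n_unhealthy = 0, n_total = 0)),
    class = "hcal_invalid_argument"
  )
  expect_error(
    smooth_prevalence(data.frame(age = 1:5, n_unhealthy = 10, n_total = 5)),
    class = "hcal_invalid_argument"
  )
  expect_error(
    smooth_prevalence(data.frame(age = 1:5, n_unhealthy = 1, n_total = 5),
                      penalty_selection = "fixed"),
    class = "hcal_invalid_argument"
  )
})

test_that("prevalence extension carries boundary values with their sample sizes", {
  sched <- data.frame(age = 16:20, pi = seq(0.1, 0.3, by = 0.05), n = 11:15)
  ext <- extend_prevalence(sched, ages = 14:22)
  expect_equal(ext$pi[ext$age < 16], c(0.1, 0.1))
  expect_equal(ext$n[ext$age < 16], c(11, 11))
  expect_equal(ext$pi[ext$age > 20], c(0.3, 0.3))
  expect_true(all(ext$extended == c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                    FALSE, FALSE, TRUE, TRUE)))
  zero <- extend_prevalence(sched, ages = 14:22, method = "zero")
  expect_equal(zero$pi[zero$age < 16], c(0, 0))
  gappy <- data.frame(age = c(16, 18), pi = c(0.1, 0.2))
  expect_error(extend_prevalence(gappy, ages = 16:18), "gaps",
               class = "hcal_invalid_argument")
})
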