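toy_lifetable <- function(Lx, radix = 1) {
  k <- length(Lx)
  structure(
    tibble::tibble(age = seq_len(k) - 1, Lx = Lx,
                   lx = rep(radix, k), ex = rep(NA_real_, k)),
    class = c("lifetable", class(tibble::tibble())),
    radix = radix, type = "period", index_year = 2000L, a0_rule = "keyfitz"
  )
}

test_that("healthy survival combines survivorship and prevalence multiplicatively", {
  out <- healthy_survival_curve(
    data.frame(age = 60, p = 0.8),
    data.frame(age = 60, pi = 0.3)
  )
  expect_equal(out$healthy, 0.8 * (1 - 0.3))

  sc <- synthetic_scenario()
  surf <- make_surface(sc, years = 1915:2015, omega = 100)
  cs <- cohort_survivorship(surf, 2015)
  zeros <- data.frame(age = 0:100, pi = 0)
  ones <- data.frame(age = 0:100, pi = 1)
  expect_equal(healthy_survival_curve(cs, zeros)$healthy, cs$p)
  expect_equal(healthy_survival_curve(cs, ones)$healthy, rep(0, 101))
})

test_that("grid mismatch and invalid prevalence are rejected with informative errors", {
  cs <- data.frame(age = 0:10, p = 1)
  expect_error(healthy_survival_curve(cs, data.frame(age = 0:9, pi = 0)),
               "grids differ", class = "hcal_invalid_argument")
  expect_error(healthy_survival_curve(cs, data.frame(age = 0:10, pi = 1.2)),
               class = "hcal_invalid_argument")
  lt <- toy_lifetable(c(0.9, 0.7, 0.2))
  expect_error(sullivan_he(lt, data.frame(age = 0:2, pi = c(0.1, NA, 0.2))),
               class = "hcal_invalid_argument")
})

test_that("Sullivan HE apportions person-years by healthy share (hand sum)", {
  lt <- toy_lifetable(c(0.9, 0.7, 0.2))
  prev <- data.frame(age = 0:2, pi = c(0.1, 0.2, 0.5))
  expect_equal(sullivan_he(lt, prev), 0.81 + 0.56 + 0.10)
})

test_that("HE is linear in the healthy share", {
  surf <- make_surface(synthetic_scenario(), years = 2014:2015, omega = 100)
  lt <- period_lifetable(surf, 2015)
  zeros <- data.frame(age = 0:100, pi = 0)
  halves <- data.frame(age = 0:100, pi = 0.5)
  expect_equal(sullivan_he(lt, zeros), lt$ex[1])
  expect_equal(sullivan_he(lt, halves), lt$ex[1] / 2)
})

test_that("HCAL reduces to CAL with zero prevalence and to HE under stationarity", {
  sc <- synthetic_scenario(improvement = 1)
  surf <- make_surface(sc, years = 1915:2015, omega = 100)
  cs <- cohort_survivorship(surf, 2015)
  lt <- period_lifetable(surf, 2015)
  zeros <- data.frame(age = 0:100, pi = 0)
  prev <- make_prevalence(sc, ages = 0:100)
  expect_identical(sullivan_hcal(cs, zeros), cal(cs))
  expect_identical(sullivan_hcal(cs, prev), sullivan_he(lt, prev))
})

test_that("HCAL equals the independent brute-force diagonal sum", {
  sc <- synthetic_scenario(improvement = 0.985)
  surf <- make_surface(sc, years = 1915:2015, omega = 100)
  cs <- cohort_survivorship(surf, 2015)
  prev <- make_prevalence(sc, ages = 0:100)
  expect_equal(sullivan_hcal(cs, prev),
               oracle_hcal(surf, 2015, prev$pi), tolerance = 1e-12)
})

test_that("dominance: lower prevalence everywhere gives more healthy years", {
  set.seed(41)
  sc <- synthetic_scenario()
  surf <- make_surface(sc, years = 1915:2015, omega = 100)
  lt <- period_lifetable(surf, 2015)
  cs <- cohort_survivorship(surf, 2015)
  for (i in 1:5) {
    pa <- runif(101, 0, 0.5)
    pb <- pa + runif(101, 0, 0.4)
    prev_a <- data.frame(age = 0:100, pi = pa)
    prev_b <- data.frame(age = 0:100, pi = pb)
    expect_gte(sullivan_he(lt, prev_a), sullivan_he(lt, prev_b))
    expect_gte(sullivan_hcal(cs, prev_a), sullivan_hcal(cs, prev_b))
    # bound chain
    expect_gte(sullivan_he(lt, prev_b), 0)
    expect_lte(sullivan_he(lt, prev_b), lt$ex[1])
    expect_gte(sullivan_hcal(cs, prev_b), 0)
    expect_lte(sullivan_hcal(cs, prev_b), cal(cs))
  }
})

test_that("relative weighting: HCAL/CAL exceeds HE/LE when cohort survivorship tilts young", {
  sc <- synthetic_scenario()  # improving mortality, prevalence rising in age
  surf <- make_surface(sc, years = 1915:2015, omega = 100)
  prev <- make_prevalence(sc, ages = 0:100)
  lt <- period_lifetable(surf, 2015)
  cs <- cohort_survivorship(surf, 2015)
  # premise: diagonal person-years are relatively heavier at young ages
  rel <- (cs$Lx / sum(cs$Lx)) - (lt$Lx / sum(lt$Lx))
  young <- lt$age < 50
  expect_gt(sum(rel[young]), 0)
  he <- sullivan_he(lt, prev)
  hcal <- sullivan_hcal(cs, prev)
  expect_gt(hcal / cal(cs), he / lt$ex[1])
})
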