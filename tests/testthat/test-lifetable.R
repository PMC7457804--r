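test_that("rate-to-probability conversion matches the standard formula and clamps", {
  expect_equal(mx_to_qx(0, 1, 0.5), 0)
  expect_equal(mx_to_qx(0.1, 1, 0.5), 0.1 / (1 + 0.5 * 0.1))
  expect_warning(q <- mx_to_qx(10, 1, 0.5), "clamped")
  expect_equal(q, 1)
  expect_error(mx_to_qx(-0.1), class = "hcal_invalid_argument")
  expect_error(mx_to_qx(0.1, 1, 0), class = "hcal_invalid_argument")
  expect_error(mx_to_qx(0.1, 1, 1.5), class = "hcal_invalid_argument")
})

test_that("zero mortality with a truncated terminal age gives e0 = omega", {
  surf <- flat_surface(0, omega = 20)
  lt <- period_lifetable(surf, 2000, close_with_exposure = FALSE)
  expect_equal(lt$ex[1], 20)
  expect_true(all(lt$lx == 1))
})

test_that("constant hazard reproduces the exponential closed form", {
  for (mu in c(0.01, 0.05)) {
    surf <- flat_surface(mu, omega = 100)
    lt <- period_lifetable(surf, 2000, a0_rule = "constant",
                           close_with_exposure = FALSE)
    truth <- (1 - exp(-mu * 100)) / mu
    expect_lt(abs(lt$ex[1] - truth), 0.05)
  }
})

test_that("discretization error shrinks from 5-year to 1-year intervals", {
  # a 5-year grid is emulated by rescaling the time unit: rate 5*mu per
  # unit over omega/5 units, then converting back to years
  for (mu in c(0.01, 0.05)) {
    truth <- (1 - exp(-mu * 100)) / mu
    fine <- period_lifetable(flat_surface(mu, omega = 100), 2000,
                             a0_rule = "constant",
                             close_with_exposure = FALSE)$ex[1]
    coarse <- 5 * period_lifetable(flat_surface(5 * mu, omega = 20), 2000,
                                   a0_rule = "constant",
                                   close_with_exposure = FALSE)$ex[1]
    expect_lt(abs(fine - truth), abs(coarse - truth))
  }
})

test_that("cohort table reads the Lexis diagonal (2x2 hand computation)", {
  # diagonal rates chosen so q(0) = 0.5 (with keyfitz a0 capped at 0.5)
  # and q(1) = 1; off-diagonal cells are poisoned to catch column reads
  surf <- mortality_surface(tibble::tibble(
    year = c(2000, 2000, 2001, 2001),
    age = c(0, 1, 0, 1),
    rate = c(2 / 3, 9, 9, 2)
  ))
  lt <- cohort_lifetable(surf, birth_year = 2000)
  expect_equal(lt$qx, c(0.5, 1))
  expect_equal(lt$lx, c(1, 0.5))
  # L(0) = 0.5 + 0.5*0.5, L(1) = l(1)/m(1) = 0.25
  expect_equal(lt$ex[1], 1.0)
})

test_that("missing years for a cohort raise a named missing-data error", {
  surf <- flat_surface(0.01, omega = 20, years = 2000:2010)
  expect_error(cohort_lifetable(surf, 2000), "2020",
               class = "hcal_missing_data")
  expect_error(period_lifetable(surf, 1999), "1999",
               class = "hcal_missing_data")
})

test_that("e0 is invariant to the radix", {
  sc <- synthetic_scenario()
  surf <- make_surface(sc, years = 2000:2001, omega = 100)
  e1 <- period_lifetable(surf, 2000, radix = 1)$ex[1]
  e2 <- period_lifetable(surf, 2000, radix = 1e5)$ex[1]
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("period and cohort tables agree exactly on a stationary surface", {
  sc <- synthetic_scenario(improvement = 1)
  surf <- make_surface(sc, years = 1950:2060, omega = 100)
  pe <- period_lifetable(surf, 1955)
  co <- cohort_lifetable(surf, birth_year = 1955)
  expect_identical(pe$ex, co$ex)
  expect_identical(pe$Lx, co$Lx)
})

test_that("person-years conserve life expectancy (sum L / l0 = e0)", {
  sc <- synthetic_scenario()
  surf <- make_surface(sc, years = 2000:2001, omega = 100)
  for (radix in c(1, 1e5)) {
    lt <- period_lifetable(surf, 2001, radix = radix)
    expect_equal(sum(lt$Lx) / radix, lt$ex[1], tolerance = 1e-12)
  }
})

test_that("life-table invariants hold on a realistic schedule", {
  surf <- make_surface(synthetic_scenario(), years = 2010:2011, omega = 100)
  lt <- period_lifetable(surf, 2010, radix = 1e5)
  expect_true(all(diff(lt$lx) <= 0))
  expect_true(all(lt$lx >= 0))
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_equal(lt$qx[nrow(lt)], 1)
  expect_equal(lt$dx, lt$lx - c(lt$lx[-1], 0))
  non_term <- seq_len(nrow(lt) - 1)
  expect_equal(lt$Lx[non_term],
               lt$lx[non_term + 1] + lt$ax[non_term] * lt$dx[non_term])
  expect_equal(lt$Tx, rev(cumsum(rev(lt$Lx))))
})

test_that("a0 rules behave as documented", {
  surf <- flat_surface(0.01, omega = 10)
  kf <- period_lifetable(surf, 2000, a0_rule = "keyfitz")
  ct <- period_lifetable(surf, 2000, a0_rule = "constant")
  expect_equal(kf$ax[1], 0.07 + 1.7 * 0.01)
  expect_equal(ct$ax[1], 0.3)
  expect_true(all(kf$ax[-1] == 0.5))
  # cap at 0.5 for very high infant mortality
  high <- flat_surface(0.5, omega = 10)
  expect_equal(period_lifetable(high, 2000)$ax[1], 0.5)
})

test_that("glance and life_expectancy expose the table summary", {
  surf <- flat_surface(0.01, omega = 10)
  lt <- period_lifetable(surf, 2000)
  g <- glance(lt)
  expect_equal(g$e0, lt$ex[1])
  expect_equal(g$type, "period")
  expect_equal(life_expectancy(lt, 5), lt$ex[lt$age == 5])
  expect_error(life_expectancy(lt, 200), class = "hcal_invalid_argument")
})
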