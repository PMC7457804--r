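---
title: "Methods: healthy life years from period and cohort survivorship"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: healthy life years from period and cohort survivorship}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcal)
```

## The measures

`hcal` computes four longevity-and-health indicators for a reference year
$t$ from two ingredients: an age-by-year surface of single-age death rates
$m(x, y)$, and an age schedule of the prevalence of poor health
$\pi(x, t)$.

**Period life expectancy.** A life table built from one calendar year's
rates. Rates convert to probabilities of dying by the standard
single-decrement formula $q = m / (1 + (1 - a)\,m)$ with separation factor
$a(x)$, survivorship accumulates as $l(x{+}1) = l(x)(1 - q(x))$,
person-years are $L(x) = l(x{+}1) + a(x)\,d(x)$, and
$e_0 = \sum_x L(x)/l_0$.

**Cross-sectional cohort survivorship and CAL.** The cohort aged $x$ at
$t$ was born in $t - x$ and lived through the cells $(a,\, t - x + a)$,
$a = 0, \dots, x-1$ of the Lexis plane. Chaining those period rates gives
$$p_c(x) = \prod_{a=0}^{x-1}\bigl(1 - q(a,\, t - x + a)\bigr),$$
and CAL$(t) = \sum_x L_c(x)$, where the diagonal person-years $L_c(x)$ are
computed within each cohort's own diagonal (its next year of exposure is
the reference year's cell $(x, t)$) with the same $a(x)$ and terminal
rules as the period table. This chaining attributes each year of age
wholly to one calendar year — period-rate chaining rather than true
triangle-level cohort rates, which keeps the data demand to the period
surfaces that national statistical series actually publish. Because
adjacent ages belong to *different* cohorts, $p_c$ need not decrease in
age: a cohort hit by a birth shock sits below its one-year-older
neighbour, and the curve visibly rises at that age. Each single cohort's
own survivorship, recomputed along its diagonal, is of course monotone.

**HE and HCAL.** The Sullivan method weights person-years by the healthy
share: $\mathrm{HE} = \sum_x (1 - \pi(x))\,L(x)/l_0$ and
$\mathrm{HCAL} = \sum_x (1 - \pi(x))\,L_c(x)/l_0^c$. The same prevalence
schedule feeds both sums; the two indicators differ only in the
survivorship they weight. HCAL pairs the health reports of real cohorts
with those same cohorts' survival histories, which is its conceptual
advantage; its price is a century of mortality history (reconstructing
ages 0–100 in year $t$ needs rates back to $t - 100$).

## Conventions and tunable parameters

- **Age grid.** Single-year ages $0..\omega$, $\omega = 100$ by default.
  Ages are completed ages (age last birthday); all intervals $[x, x+1)$
  are half-open. Abridged tables are out of scope.
- **Separation factors.** $a(x) = 0.5$ for all ages except age 0, where
  `a0_rule` selects Keyfitz's infant rule $a_0 = 0.07 + 1.7\,m(0)$ capped
  at 0.5 (default) or a constant 0.3. Published tables rarely state their
  factors, so both standard options are exposed.
- **Terminal age.** $q(\omega) = 1$ always. `close_with_exposure = TRUE`
  (default) closes the table with $L(\omega) = l(\omega)/m(\omega)$, the
  exponential-exposure convention; `FALSE` truncates at $\omega$
  ($L(\omega) = 0$), which is the right comparison point for closed-form
  integrals truncated at $\omega$.
- **Radix.** Defaults to 1, so `lx` is a survivorship probability and the
  cohort reconstruction's convention $l_0^c = 1$ matches the period table
  without rescaling. $e_0$ and all Sullivan measures are radix-invariant.
- **Rate-to-probability clamping.** Very high rates (possible at extreme
  ages in raw historical data) can push $q$ past 1; values are clamped to
  $[0, 1]$ with a warning rather than an error, since a hard failure on a
  handful of extreme-age cells would make whole surfaces unusable.
- **Prevalence extension.** Surveys cover part of the age range (16+ for
  the household surveys this mirrors). `extend_prevalence()` carries the
  youngest observed value downward (default) or fills zeros, and always
  carries the oldest value upward; extended rows keep the boundary age's
  sample size and are flagged. See the caveat under *Limitations*.

## Prevalence smoothing

Single-age prevalence from a few hundred respondents per age fluctuates
strongly. `smooth_prevalence()` fits a P-spline: cubic B-splines on knots
every 5 years of age, a second-order difference penalty on the
coefficients, and penalized IRLS for the binomial counts (unhealthy out of
total per age). The penalty weight is chosen by BIC
($\mathrm{dev} + \log(n)\,\mathrm{ED}$) over the grid
$10^{\{-2,\dots,4\}}$ (13 log-spaced points). The two-dimensional variant
uses a tensor-product basis over age and calendar year with separate
penalties per dimension, selected on the same grid, for populations with
several consecutive survey years free of breaks; series with breaks or
outliers should be smoothed year by year (`age_1d`), mirroring the manual
curation such data requires. The binomial likelihood is the exact model
for proportions; for small prevalence it coincides with the Poisson count
smoothing commonly used for mortality surfaces.

Numerical details: coefficients start from the empirical logits of
$(c + 1/2)/(N + 1)$; a $10^{-8}$ ridge stabilizes the penalized normal
equations when columns are weakly supported; fitted probabilities are
clipped to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$;
non-convergence after 100 IRLS steps is an error carrying the last step
size. When the year basis is too small to carry a second-order penalty
(two observed years), the year penalty is empty and the 2D fit separates
exactly into per-year 1D fits — a property the tests exploit.

## Uncertainty

Prevalence variances use the binomial approximation
$\widehat{\mathrm{Var}}(\pi(x)) = \pi(x)(1-\pi(x))/N(x)$ with the
*smoothed* $\pi$ and the *observed* per-age count $N(x)$, and propagate
through the Sullivan sum as
$\mathrm{Var} = \sum_x L(x)^2\,\mathrm{Var}(\pi(x)) / l_0^2$; the same
formula with $L_c(x)$ applies to HCAL, the natural analogue since HCAL is
the same linear functional of $\pi$. Intervals are $\pm 1.96\,$SE.
Mortality-rate uncertainty is ignored — for vital-registration surfaces
it is negligible next to the survey noise — and so is the correlation
across ages induced by smoothing (independent-ages approximation). A full
survey bootstrap is used as the oracle in the test suite, not as a user
path.

## The synthetic generator

`synthetic_scenario()` defines a world with known truth:

- hazard $(c + a e^{b x})\,\rho^{\,y - y_{\mathrm{anchor}}}$ —
  Gompertz–Makeham in age, geometric secular improvement in time,
  deterministic (mortality is treated as fixed data; all sampling noise
  lives in the surveys);
- an optional birth-cohort shock multiplying the rates on chosen Lexis
  diagonals, to reproduce the non-monotone $p_c$;
- a logistic limitation curve
  $\pi(x) = \mathrm{floor} + (\mathrm{ceiling}-\mathrm{floor})/(1 + e^{-s(x - x_0)})$;
- binomial survey draws per age with optional lognormal weights.

The packaged default (`scenario_france_like()`) uses $c = 10^{-3}$,
$a = 1.5\times 10^{-5}$, $b = 0.10$, $\rho = 0.98$, chosen by a coarse
grid search so that the 2015 period $e_0$ is about 79 years and CAL about
74 years — the order of magnitude of a Western European male population —
with a logistic prevalence rising from 5% to 60% around age 60 and 500
respondents per age. What the generator does *not* emulate: cause
structure, migration, period shocks (wars, epidemics) other than the
single cohort shock, reporting heterogeneity and survey design effects
beyond weights, and breaks in health-series comparability. Passing tests
therefore certify the estimators' arithmetic and statistical calibration
under clean conditions, not robustness to the measurement problems of
real survey series.

## Design choices where the design was open

- **Chaining from rates, not published q.** The reconstruction defaults to
  raw $m$ cells converted internally; published probabilities can be fed
  through the same conversion inverse if that is what a source provides.
- **Bit-exact stationarity.** Period, cohort and diagonal computations
  share one arithmetic path (same multiplication order, same accumulation
  order for the person-years sums), so on a time-constant surface period
  LE, cohort LE, CAL coincide *bit for bit*, and HE equals HCAL likewise.
  The test suite asserts identity, not closeness.
- **Truncation is explicit.** A surface without enough history is a hard
  error naming the earliest year required; `allow_truncated` computes a
  truncated reconstruction but flags it, and `cal()` warns, because a
  truncated CAL is a different measure, not an approximation.
- **No silent regridding.** Survivorship and prevalence must share the age
  grid exactly; alignment (including extension over uncovered ages) is an
  explicit, flagged step.

## Problem sizes in the test suite

The suite runs surfaces of $101 \times 101$ cells (ages 0–100, a century
of years), Monte-Carlo recovery with 20 replicates for curve recovery,
500 for the variance comparison and 200 for interval coverage at 500
respondents per age — sizes at which the whole suite completes in well
under a minute while keeping Monte-Carlo error a small fraction of the
tolerances tested.

## Limitations

- **Extension bias at the survey floor.** The P-spline fit has a small
  boundary bias at the youngest observed age; holding that value constant
  down to age 0 multiplies the bias by the number of filled ages. In the
  packaged scenario this shifts HE by about +0.1 years and pulls the
  nominal 95% interval's coverage to roughly 87%; when the survey covers
  the whole age range, coverage is on the nominal mark. Interval coverage
  should be read as a statement about the variance approximation, with
  the extension convention a separate, bias-type caveat.
- **Indistinguishability is regime-dependent.** Whether HE and HCAL are
  statistically distinguishable depends on the size of the LE–CAL gap
  relative to survey noise. Under mild improvement (fractions of a percent
  per year) the two indicators' intervals overlap at household-survey
  sample sizes; under the packaged 2%-per-year improvement the concept gap
  (about 2.7 years) dwarfs the intervals (about ±0.5 years) and the
  indicators separate clearly. Neither outcome is an artefact; the tests
  pin the overlap claim to the regime where it holds.
- **Prevalence-based, not incidence-based.** Like every Sullivan-type
  measure, HE and HCAL reflect the current stock of ill-health, not
  transition rates, and react sluggishly to sudden changes in population
  health regardless of the survivorship used.
- The independent-ages variance ignores smoothing-induced correlation;
  the bootstrap oracle in the tests bounds the resulting error at the
  packaged sample sizes (analytic SE within 15% of the empirical SD).
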