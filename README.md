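# hcal

Healthy life years on two mortality foundations: the conventional period
life table and the cross-sectional average length of life (CAL).

## The problem

The most widely used indicator of population health, health expectancy
(HE), applies the Sullivan method: person-years lived in a period life
table are apportioned into healthy and unhealthy years using age-specific
prevalence of activity limitation from cross-sectional surveys. But the
period life table describes a *hypothetical* cohort exposed forever to one
year's death rates, while the survey respondents are *real* cohorts, each
with its own mortality history. `hcal` implements the variant that removes
this mismatch: it replaces the period survivorship with the
cross-sectional cohort survivorship underlying CAL, in which the cohort
aged x in year t carries the death rates it actually experienced along its
Lexis diagonal. The resulting indicator is the cross-sectional average
length of healthy life (HCAL).

In standard notation, with survivorship functions p(x, t) (period) and
p_c(x, t − x) (cohort reaching age x at t), and π(x, t) the prevalence of
poor health:

    LE(t)   = ∫ p(x, t) dx                      CAL(t)  = ∫ p_c(x, t − x) dx
    HE(t)   = ∫ p(x, t) (1 − π(x, t)) dx        HCAL(t) = ∫ p_c(x, t − x) (1 − π(x, t)) dx

Discretely, HE = Σ (1 − π(x)) L(x) / l0 over single ages with period
person-years L(x), and HCAL uses the diagonal cohort person-years L_c(x)
instead. The same prevalence schedule feeds both measures.

The package covers the full pipeline:

- **Life tables** — single-age period and real-cohort tables
  (mx → qx → lx → Lx → ex) from an age-by-year surface of death rates.
- **Cohort survivorship / CAL** — reconstruction of p_c by chaining period
  rates along Lexis diagonals (a century of history for ω = 100), and its
  integral CAL; truncated reconstructions on request.
- **Sullivan measures** — HE, HCAL, healthy-survival curves, health
  summaries, time-change and gender-gap comparisons.
- **Prevalence smoothing** — weighted tabulation of survey microdata and
  penalized B-spline (P-spline) smoothing of the binomial counts over age,
  or jointly over age and year, with BIC-selected penalties.
- **Uncertainty** — binomial prevalence variances propagated through the
  Sullivan sum to standard errors and 95% intervals for HE and HCAL.
- **Synthetic data** — a Gompertz–Makeham generator with secular
  improvement, cohort shocks, a logistic limitation curve and survey
  sampling, so that every estimate can be checked against a known truth.
- **I/O** — HMD-style `Mx_1x1` rate files (read), long-form `year,age,rate`
  CSV (read/write), prevalence CSVs, flat CSV/JSON result records, and
  surface splicing across sources.

## Worked example

```r
library(hcal)

sc    <- scenario_france_like()                       # e0 ~ 79, CAL ~ 74
surf  <- make_surface(sc, years = 1915:2015, omega = 100)
truth <- make_prevalence(sc, ages = 16:100)
svy   <- draw_survey(truth, n_per_age = 500, seed = 2015)
sm    <- smooth_prevalence(tabulate_prevalence(svy))
health_summary(surf, sm, year = 2015, population = "france_like")
#> <health_summary> france_like 2015 (synthetic): LE 79.40 | HE 63.24 | CAL 74.56 | HCAL 60.52
```

CAL (74.56) sits below period LE (79.40) because it still carries the
higher historical rates the living cohorts actually experienced, and HCAL
(60.52) is correspondingly below HE (63.24). In relative terms the order
reverses — HCAL/CAL = 81.2% versus HE/LE = 79.7% — because the diagonal
person-years weight the young, low-prevalence ages relatively more
heavily. Comparing 2015 against 2008 on the same surface:

```r
s08 <- health_summary(make_surface(sc, years = 1908:2015, omega = 100),
                      sm, year = 2008, population = "france_like")
compare_summaries(health_summary(surf, sm, 2015, population = "france_like"),
                  s08, mode = "time_change")
#>   measure  value_a value_b            units  difference
#>   le        79.40   77.60   years              1.80
#>   he        63.24   62.27   years              0.98
#>   cal       74.56   72.59   years              1.97
#>   hcal      60.52   59.39   years              1.13
#>   ratio_he_le    79.66 80.24 percentage points  -0.58
#>   ratio_hcal_cal 81.18 81.82 percentage points  -0.64
```

CAL gains faster than LE (it averages improvement over all living
cohorts), so HCAL gains more healthy years than HE while its healthy-share
ratio declines slightly faster — the characteristic behaviour of the two
indicators under steady mortality improvement with unchanged prevalence.

A thin command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hcal.R", package = "hcal"))')" \
  simulate --out-dir sim --seed 7 --years 1915:2015
```

with subcommands `lifetable`, `cal`, `sullivan`, `smooth`, `simulate` and
`compare`, YAML config support, and byte-reproducible outputs under a
fixed seed.

## File formats

- Mortality surface (native): CSV `year,age,rate`, one row per cell,
  single ages 0..ω, contiguous years; empty rate = missing.
- HMD `Mx_1x1` (read-only): header lines, then
  `Year Age Female Male Total`, `110+` open group, `.` for missing.
- Prevalence: microdata `age[,year],unhealthy[,weight]` or tabulated
  `age[,year],n_unhealthy,n_total`.
- Results: flat CSV/JSON with one record per population-year-sex
  (`le, he, cal, hcal, ratio_he_le, ratio_hcal_cal` and `*_se`,
  `*_lo95`, `*_hi95` columns).

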