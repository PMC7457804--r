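Package: hcal
Title: Healthy Life Years from Period and Cross-Sectional Cohort Survivorship
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing healthy-life-years indicators with the
    Sullivan method on two mortality foundations: the conventional period
    life table (health expectancy, HE) and the cross-sectional average
    length of life (CAL), which chains observed period death rates
    longitudinally along Lexis diagonals to obtain the survivorship of the
    real cohorts alive in a reference year (HCAL). Includes single-age
    period and cohort life-table construction, cohort-survivorship
    reconstruction from age-by-year mortality surfaces, penalized B-spline
    smoothing of age-specific health prevalence from survey microdata,
    analytic standard errors and confidence intervals for HE and HCAL,
    readers for Human Mortality Database style rate files, and a synthetic
    data generator with known ground truth for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
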