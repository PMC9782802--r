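Package: lifetabler
Title: Age-Stage Two-Sex Life Tables, Bootstrap Inference, and Probit
    Dose-Response for Insect Cohort Bioassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes age-stage, two-sex life table parameters from
    individual-level insect rearing records: age-stage survival and
    fecundity matrices, age-specific survival (lx) and fecundity (mx)
    schedules, net and gross reproductive rates, the intrinsic rate of
    increase solved from the Euler-Lotka equation by bisection, the
    finite rate of increase, mean generation time, and pre-oviposition
    periods. Uncertainty for every demographic parameter is obtained by
    bootstrap resampling of individuals, with percentile confidence
    intervals and bootstrap group comparisons. A probit dose-response
    module fits binomial mortality on log10 dose by maximum likelihood
    and reports lethal concentrations (LC50, LC90) with 95% fiducial
    limits via Fieller's theorem, heterogeneity-adjusted. A
    stage-structured cohort simulator with exact expected schedules
    supports parameter-recovery testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
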