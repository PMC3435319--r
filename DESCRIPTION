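Package: saltcvd
Title: Markov Cohort Modelling of Dietary Salt Reduction and Cardiovascular
    Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Open-cohort Markov (state-transition) model of myocardial
    infarction and stroke among adults aged 40-69 in India, projecting the
    cardiovascular impact of population-wide dietary salt reduction. The
    model advances twelve gender-, age- and location-stratified cohorts
    through seven health states in monthly steps with competing risks,
    secular trends, aging and new entrants. Salt scenarios act through a
    two-stage exposure chain (salt to systolic blood pressure to relative
    risk) with lagged phase-in of benefit. Includes a synthetic input
    generator with calibration to aggregate totals, an iodine-deficiency
    side model, outcome aggregation (averted events, rates per 10,000,
    subgroup shares) and multivariate probabilistic sensitivity analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
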