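Package: hfcoi
Title: Cost-of-Illness Analysis for Heart Failure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Prevalence-based and incidence-based cost-of-illness analysis
    for heart failure cohorts. Implements bottom-up annual costing with
    human-capital indirect components (absenteeism, presenteeism, unpaid
    work, job change, premature death), a six-state Markov cohort model
    (NYHA I-IV plus two absorbing death states) for lifetime costs with
    per-state attribution, and a two-part regression (probit for any-cost,
    log-link GLM for positive costs) for semicontinuous expenditure data.
    A seeded synthetic-cohort generator calibrated by moment inversion of
    zero-inflated cost mixtures makes every stage testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
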