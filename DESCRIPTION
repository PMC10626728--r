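Package: hfcea
Title: Markov Cohort Cost-Effectiveness Analysis of Digital Home-Based
    Cardiac Rehabilitation in Chronic Heart Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decision-analytic modelling pipeline for the cost-effectiveness
    of digitally delivered (app-guided) home-based cardiac rehabilitation
    versus conventional home-based rehabilitation in chronic heart failure.
    Implements a five-state NYHA Markov cohort model with monthly cycles and
    discounted cost and QALY accrual, incremental cost-effectiveness ratios
    and net monetary benefit, deterministic one-way (tornado) and two-way
    sensitivity analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, a built-in published parameter
    set, a synthetic-instance generator, and an individual-level
    microsimulation oracle for validating the cohort engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
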