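Package: transurv
Title: Transductive Semi-Supervised Regression for Right-Censored Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-supervised survival modelling in which censored
    training targets are transduced: each censored observation's target time is
    searched over a grid between its censoring time and the maximum observed
    time, keeping the candidate that maximizes a combined concordance /
    classification criterion evaluated against the original observed times.
    Includes two censoring-aware base learners (a Cox proportional-hazards
    model fit by Newton-Raphson on the Breslow partial likelihood, and support
    vector regression with asymmetric slack penalties and epsilon-tubes for
    censored records), concordance-index and time-point stratification
    metrics, a two-endpoint disease-progression simulator, and an experiment
    pipeline that trains on an early endpoint and validates on early and late
    endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    kernlab,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
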