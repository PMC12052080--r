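Package: hypoalert
Title: Evaluation of Intraoperative Hypotension Alert Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate predictors of intraoperative hypotension on
    20-second mean arterial pressure (MAP) time series: detection of
    hypotensive events (MAP < 65 mmHg for at least one minute) and of
    blood-pressure-raising intervention artefacts; construction of alert
    episodes for index thresholds (e.g. a 0-100 hypotension index at >= 85),
    MAP thresholds in the 70-75 mmHg range with optional 40-second
    time-dependence, and linear-extrapolation (LepMAP0) forecasts with a
    time-to-event extension; adjacency- and timeframe-oriented
    true/false-positive classification with intervention-superseded alert
    exclusion; and time-to-event, positive predictive value and missed-event
    metrics with patient-level bootstrap confidence intervals and paired
    time-gain comparisons. A calibrated synthetic-cohort generator emulates
    the statistical structure of an intraoperative cohort so the full
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
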