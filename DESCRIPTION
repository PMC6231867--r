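Package: trialcua
Title: Cost-Utility Analysis Alongside Two-Arm Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for trial-based economic evaluation from a societal
    perspective: EQ-5D-3L profile scoring against configurable value sets
    (the Dutch time trade-off tariff is bundled), last-observation-carried-
    forward imputation and trapezoidal quality-adjusted life-year (QALY)
    computation, per-patient societal costing (health-care resource use,
    medication, travel, friction-method absenteeism and presenteeism, and
    amortized intervention costs), and bootstrap incremental cost-utility
    analysis with cost-effectiveness plane quadrants and acceptability
    curves. A calibrated synthetic cohort generator emulates the statistical
    structure of a two-arm trial so the whole pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
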