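Package: surgworkload
Title: Preoperative Surgical Workload Assessment by Normal-Based Linear
    Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs preoperative assessment rules for surgical workload
    in hand-assisted laparoscopic donor nephrectomy (and similar settings)
    from donor clinical and CT-derived variables. Implements the
    normal-based linear discriminant rule (two-class Gaussian classifier
    with shared covariance and prior odds), exhaustive best-subset search
    over all non-empty predictor subsets, leave-one-out cross-validation
    and the Efron .632 bootstrap estimator of true hit rates, threshold
    adequacy sweeps across operative-time percentiles, supporting
    association statistics (linear regression, correlations, group
    comparisons, exact contingency tests), and a calibrated synthetic
    cohort generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
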