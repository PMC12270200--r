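Package: parkscreen
Title: Multimodal Parkinson's Disease Screening with Uncertainty-Calibrated Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating multimodal screening models for
    Parkinson's disease from tabular task features (finger tapping, smile,
    speech). Implements uncertainty-aware shallow classifiers with Monte-Carlo
    dropout, an uncertainty-calibrated attention fusion network with selective
    prediction (withholding of uncertain verdicts), a genetic-algorithm
    demographic cohort balancer, minority oversampling, and a diagnostic
    evaluation suite (bootstrap confidence intervals, calibration metrics,
    inter-rater agreement, subgroup statistics). Ships a synthetic multimodal
    cohort generator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
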