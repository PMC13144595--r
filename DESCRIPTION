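Package: uqeval
Title: Uncertainty Quantification for Clinical Outcome Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate predictive-uncertainty methods (Monte Carlo
    dropout, deep ensembles, test-time augmentation) and uncertainty measures
    (binary entropy, variance, mutual information) for binary clinical outcome
    prediction models of the NTCP/TCP type. Includes a synthetic cohort
    generator with known per-patient event probabilities, a small dropout-capable
    feed-forward classifier, adaptive-bin calibration error (ACE), DeLong
    comparison of correlated AUCs, sparsification analysis, and an orchestrated
    training-set-size experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
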