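Package: fedcopd
Title: Simulated Federated Averaging for COPD Severity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-process simulator of federated averaging (FedAvg) for
    binary severity classification of acute exacerbations of chronic
    obstructive pulmonary disease (AECOPD) from tabular clinical records.
    Provides a synthetic cohort generator that reproduces published
    group-level summary statistics (group sizes, sex counts, 95 percent
    confidence intervals of vital-sign means), preprocessing filters for
    missing data, a small fully connected classifier trained by minibatch
    gradient descent on binary cross-entropy, the federated-averaging
    communication loop across simulated hospitals, an isolated per-site
    training baseline, threshold and ranking metrics (accuracy, precision,
    recall, F1, ROC/AUC), and seeded experiment runners for comparisons,
    hyperparameter sweeps and repeated randomized trials.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
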