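Package: qsarcalib
Title: Uncertainty Quantification and Probability Calibration for Binary
    Bioactivity Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating calibrated binary
    drug-target activity classifiers on sparse molecular fingerprints.
    Provides Tanimoto leader clustering and cluster-atomic
    cross-validation folds, a two-layer multilayer perceptron baseline
    with dropout and early stopping, train-time uncertainty
    quantification by Monte Carlo dropout and deep ensembles, a
    Hamiltonian Monte Carlo Bayesian last layer (Bayesian logistic
    regression on the frozen hidden features, preconditioned by the
    maximum a posteriori Hessian), post hoc Platt scaling including
    stacking on averaged-probability models, a calibration metric suite
    (binary cross-entropy, Brier score and its reliability/resolution
    decomposition, expected and adaptive calibration error, AUC,
    accuracy), calibration-aware hyperparameter selection, and a
    synthetic-data generator with known logistic ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ChemmineOB,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
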