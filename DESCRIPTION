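Package: shapfp
Title: Shapley Value Explanations for Fingerprint-Based Activity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Local feature attribution for machine-learning models of
    compound activity and potency built on binary molecular fingerprints.
    Provides exact Shapley values by subset enumeration, the model-agnostic
    kernel SHAP estimator (Shapley-kernel weighted least squares over
    sampled feature coalitions), and the exact polynomial-time tree SHAP
    algorithm for decision-tree ensembles, together with folded circular
    fingerprints that record which hashed bit encodes which atom
    environment (as SMARTS patterns), minimal tree-ensemble trainers and a
    JSON interchange schema, method-agreement and feature addition/removal
    evaluation machinery, per-output explanation of multi-target
    predictors, and synthetic planted-feature data generators with known
    ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ChemmineR,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    data.table,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
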