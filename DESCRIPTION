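Package: deepmpm
Title: Interpretable Mortality-Risk Prediction from Longitudinal Coded EHR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits DeepMPM, an interpretable mortality-risk model for
    longitudinal coded electronic health records. Hospital visits carry
    multi-hot ICD-9 diagnosis and DRG treatment codes which are embedded by
    a ReLU encoder (optionally initialised by intra-visit skip-gram
    pretraining), fed through a time-aware Care-LSTM whose gates receive
    treatment embeddings, admission-type weights and scaled inter-visit
    intervals, and summarised by a two-level attention mechanism
    (visit-level softmax and variable-level tanh weights) modulated by a
    harmonic recency weight. Includes readers for MIMIC-III-style CSV
    tables, the cohort cleaning and encoding rules, a synthetic cohort
    generator with comorbidity block structure, mini-batch Adadelta
    training with a slanted triangular learning-rate schedule, stratified
    cross-validation, evaluation metrics, hard-positive-example analysis
    and attention-based interpretability reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
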