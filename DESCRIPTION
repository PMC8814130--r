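Package: octcsc
Title: Two-Stage Classification of Central Serous Chorioretinopathy from
    SD-OCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies a patient's 25-slice spectral-domain optical
    coherence tomography (SD-OCT) volume as acute central serous
    chorioretinopathy (CSC), chronic CSC, or normal with a hierarchical
    two-stage system: a single-image prediction (SIP) network trained on
    lesion cuts only emits a 3-way softmax per B-scan, and a final-decision
    (FD) classifier maps the stacked 25 x 3 softmax matrix to the case
    label. Includes end-to-end 3D-CNN and CNN-LSTM comparison models,
    patient-level stratified fivefold cross-validation with a 75/25 SIP/FD
    training split, metric reporting (confusion matrix, accuracy,
    sensitivity, specificity, Cohen's kappa), deterministic preprocessing
    and train-time augmentation, and a seeded synthetic OCT-volume
    generator with per-slice lesion annotations so the whole pipeline is
    trainable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    e1071,
    randomForest,
    xgboost,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
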