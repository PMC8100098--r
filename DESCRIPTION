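Package: seavote
Title: Multi-Voting Similarity-Ensemble Target Prediction and Kinome Panel
    Analysis for Multi-Component Preparations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts direct protein targets of multi-component drug
    preparations with a five-fingerprint similarity ensemble (SEA) voting
    scheme: binary fingerprints and Tanimoto similarity, randomized
    background calibration of the SEA raw score, extreme-value p-values and
    E-values, and cross-model vote counting. Candidate targets are merged
    with known database annotations, restricted to the kinome through an
    external prediction table or a built-in similarity surrogate, and
    kinase-panel residual-activity data are analysed by threshold
    screening, dose-dependence flagging and four-parameter logistic IC50
    fitting. Includes a synthetic-data generator with planted
    compound-target structure so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
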