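Package: painattn
Title: Chronic Pain Risk Prediction from EHR Code Sequences with an
    Attention Encoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for predicting chronic pain
    within three years of a breast-cancer diagnosis from longitudinal
    electronic health records. Implements a computable chronic-pain
    phenotype (diagnosis-code rules, an opioid exposure-duration rule and
    a pain-score exacerbation rule), feature preparation for
    diagnosis-code time series (tokenization, truncation/padding,
    one-hot static encodings, variance-threshold selection), an
    encoder-only self-attention classifier over code sequences with
    positional and days-to-diagnosis embeddings fused with static
    demographic and survey branches, imbalance-weighted training,
    evaluation metrics, permutation feature importance and attention
    connection analysis. Ships a synthetic OMOP-style cohort generator
    with a planted logistic risk signal so the full pipeline is testable
    without access-restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
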