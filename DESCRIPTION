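Package: corrACF
Title: Missing-Value Tolerant Classification with Average Correlations as
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of omics samples with arbitrarily many missing
    values, without imputation. Pairwise sample correlations are computed
    under pairwise deletion and summarized into class-wise average
    correlations, on which a tunable baseline classifier (support-vector,
    random-forest or ridge) is trained (ACF). Variants subsample reference
    instances per class for constant-time prediction (F-ACF) or mask known
    biased correlations such as same-batch pairs (B-ACF). Includes the
    correlation-based comparators KNN (with optional random oversampling)
    and distribution-based classification (DBC/F-DBC), a block-structured
    correlation simulator with controlled noise and MCAR missingness, and
    an evaluation harness with repeated stratified cross-validation,
    seeded hyperparameter search, macro-F1 scoring and corrected paired
    t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    e1071,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
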