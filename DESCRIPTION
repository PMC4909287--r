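Package: esvmrfe
Title: Ensemble SVM Recursive Feature Elimination for Gene Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Backward feature elimination for high-dimensional expression
    data in which, at every elimination step, per-feature squared-weight
    rankings from many linear support vector machines trained on
    class-balanced bootstrap bags are aggregated before the weakest
    fraction of features is discarded.  Includes the classic single-model
    SVM-RFE as a degenerate configuration, leave-one-out AUC selection of
    the feature-subset size, bootstrap test-set AUC evaluation with
    quartile summaries and paired t-tests, SVD-based low-dimensional views
    of selected features with projection of held-out samples, and a
    synthetic microarray-like data generator with known informative
    features.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
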