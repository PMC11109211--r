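Package: resbias
Title: Quantifying Data-Leakage Bias from Class-Rebalancing Resampling in
    Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure how much applying class-rebalancing resampling
    (SMOTE, MWMOTE, polynomial-fit SMOTE, random over-/undersampling, Tomek
    links) to a whole dataset before cross-validation inflates predictive
    performance and calibration, relative to applying it correctly inside the
    cross-validation loop. Provides a synthetic generator for radiomics-like
    tabular data with binary outcomes, provenance-tracked implementations of
    seven resampling methods, a feature-scoring and classification grid with
    repeated stratified cross-validation under paired correct and leaky
    protocols, bias statistics with balance-association tests, and a
    random-label simulation that quantifies the leakage bias of SMOTE as a
    function of class imbalance and sample size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    ranger,
    class,
    withr,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2,
    optparse
Config/testthat/edition: 3
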