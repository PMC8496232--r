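Package: qtlgp
Title: Genomic Prediction and QTL Detection in Four-Way Outbred Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and benchmarking toolkit for genomic prediction and
    QTL detection in an outbred bi-parental (pseudo-F1, four-way) progeny.
    Simulates fully informative abxcd genotypes along a genetic map, encodes
    them into additive and dominance design matrices, and simulates pairs of
    correlated quantitative traits under configurable QTL architectures with
    heritability-deduced error variance.  Fits simple and multiple interval
    mapping (Haley-Knott regression with permutation-based LOD thresholds)
    and penalized regressions (ridge, LASSO, elastic net, and their
    multi-response group-penalized counterparts), with robust marker
    selection by stability selection and marginal false discovery rate
    control.  Evaluates prediction by nested cross-validation and marker
    selection by ROC curves and partial AUC, and calls consensus highly
    reliable QTL intervals with linkage-disequilibrium expansion and
    physical-coordinate conversion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
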