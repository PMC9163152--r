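Package: spcacox
Title: Sparse Principal Component Cox Regression for Correlated
    Environmental Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Survival inference for highly multicollinear exposure
    mixtures. Provides a block-correlated synthetic cohort generator with
    proportional-hazards outcomes, standardization with winsorization,
    dense principal component analysis and sparse principal component
    analysis by variable projection with elastic-net penalties,
    disjoint-support penalty selection, Cox proportional-hazards
    estimation with Efron tie handling and an L1-penalized coefficient
    path, back-tracing of significant components to their constituent
    variables in raw exposure units, hazard-ratio rescaling, and a decile
    exposure-response stage, orchestrated by an end-to-end four-model
    comparison pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
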