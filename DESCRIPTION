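Package: scdapower
Title: Power Analysis for Differential Abundance in Multi-Sample Single-Cell Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates batch, sample, and residual variance structure and
    cluster-frequency variation from a prototype single-cell dataset in
    principal-component (PC) space, simulates arbitrarily many multi-sample
    case-control datasets with induced cluster expansions, and estimates the
    statistical power to detect differential abundance via shared-nearest-neighbor
    Louvain re-clustering and logistic mixed-model association testing (MASC).
    Includes a synthetic prototype generator with known ground truth for
    validation, and a pipeline runner for study-design grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
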