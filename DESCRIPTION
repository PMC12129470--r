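Package: ssdselect
Title: Variable Selection Benchmarking with Supersaturated-Design
    Contrast Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing variable-selection methods for descriptive
    linear modeling of observational data.  Implements an iterative
    confidence-interval screening method adapted from supersaturated-design
    contrast analysis to continuous predictors (SSD-CI), alongside a
    comparison battery of backward elimination (p-value, AIC, BIC),
    coordinate-descent penalized regression (lasso, adaptive lasso, elastic
    net, SCAD, MCP) with 10-fold cross-validation, and (iterative) sure
    independence screening.  Includes a configurable synthetic-data
    generator for sparse linear models with correlated transformed-Gaussian
    predictors, Monte-Carlo selection-performance metrics (type I/II error,
    inclusion frequency, bias, RMSE), resampling-based stability measures
    (inclusion frequency, relative conditional bias, RMSD ratio), and a
    simulation harness with a resumable archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
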