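Package: rrpersist
Title: Random Regression Models and Persistence Indexing for Multi-Harvest Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Longitudinal genetic analysis of multi-harvest yield trials of
    clonally propagated crops. Fits random regression mixed models on
    normalized Legendre polynomial bases by restricted maximum likelihood
    (REML), with genotype and plot-level permanent-environment random
    regressions and homogeneous, harvest-diagonal or unstructured residual
    covariance. Provides model selection by the Schwarz Bayesian information
    criterion and likelihood ratio tests, covariance-function extraction
    (genetic and permanent-environment variance trajectories, heritability,
    BLUP genetic values with prediction accuracy, eigenfunctions of the
    genetic covariance function), and a genotype-ideotype persistence index
    that ranks clones by sustained genetic merit across harvests. Includes a
    synthetic clone-trial generator with known truth for validation, and an
    end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
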