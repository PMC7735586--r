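Package: peabench
Title: Imputation Benchmarking for Proximity Extension Assay Proteomics
Version: 0.1.0
Authors@R:
    person("GMP", "Proteomics Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking missing-value imputation in targeted
    proteomics data from proximity extension assays (Olink-style NPX
    matrices). Provides a synthetic NPX data generator with latent-factor
    protein covariance, chip structure, duplicate assays and per-assay
    limit-of-detection censoring; quality-control screens (PCA outliers,
    duplicate-assay concordance, malfunctioning-chip detection) that
    construct missing-completely-at-random masks; four imputation
    algorithms (column mean, random draw, iterative random forest with
    out-of-bag error estimates, and a Gibbs sampler with elastic-net
    conditional means and truncated-normal draws); accuracy evaluation
    (NRMSE, relative variance, correlation stratified by below-LOD
    fraction) with panel-subset and sample-size experiments; and a
    downstream simulation quantifying power and bias effects of imputation
    versus complete-case analysis in univariate regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
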