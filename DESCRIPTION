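Package: mmgp
Title: Multimodal Genomic Prediction for Plant Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction toolkit for multi-year, multi-environment wheat
    trials that links marker data with aerial canopy phenotypes. Provides SNP
    quality control and VanRaden genomic relationship matrices with Cholesky
    feature transforms; a Bayesian GBLUP reaction-norm model (year, line and
    year-by-line effects plus NDVI covariates) fitted by Gibbs sampling; a
    multimodal residual multilayer-perceptron with one tower per input modality
    (year, genomic, NDVI) trained with Adam, batch normalization, dropout and L2
    regularization; Gaussian-process Bayesian hyperparameter optimization;
    stochastic gradient-boosting and linear epsilon-insensitive support-vector
    regression baselines; five-fold and leave-one-year/environment-out
    cross-validation with NRMSEP and Pearson-correlation metrics; and a
    synthetic trial generator so every component is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lhs,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab
Config/testthat/edition: 3
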