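Package: kernaft
Title: Kernel Ridge Regression for Accelerated Failure Time Models with
    Right-Censored, Ultra-High Dimensional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits accelerated failure time (AFT) models to right-censored
    survival data by kernel ridge regression solved in the dual, so that the
    cost of a fit scales with the number of samples rather than the number of
    features. Provides a censored dual kernel ridge regression (DKRR) solver
    with linear, radial basis function, polynomial and sigmoid kernels, and an
    adaptive kernel ridge regression (AKRR) that performs simultaneous
    Lp-penalised (p <= 1) variable selection and estimation for n << m
    problems such as survival-associated gene selection from microarray data.
    Includes a censored-survival simulation generator with autoregressive
    covariate correlation and uniform multiplicative censoring, relative root
    mean squared error evaluation, cross-validated (lambda, p) selection with
    relevance counts, replicate selection studies, and a small command line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
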