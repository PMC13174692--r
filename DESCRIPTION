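Package: siqreg
Title: Scale-Independent Quantile Regression for Phenotype Scale Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a trait-specific Box-Cox phenotype scale by minimizing
    heterogeneity of quantile-regression coefficients across quantile levels
    (scale-independent quantile regression, SIQReg). Provides convolution-
    smoothed quantile regression with multiplier-bootstrap covariance, a Wald
    test of quantile-dependent predictor effects, a Gaussian-likelihood
    (warped) comparator estimator, subsampling confidence intervals,
    inverse-variance meta-analysis across covariates, and a simulation
    toolkit generating phenotypes from a latent additive model via the
    inverse Box-Cox map with Gaussian, Student-t, or genotype-heteroscedastic
    errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
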