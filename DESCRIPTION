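Package: restdcm
Title: Spectral Dynamic Causal Modelling of Resting-State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inversion of directed effective-connectivity models
    for resting-state BOLD time series. Provides a balloon-model forward
    simulator driven by power-law endogenous fluctuations, cross-spectral
    feature extraction (multivariate autoregressive and Welch estimators,
    discrete cosine bases, principal eigenvariates), a spectral dynamic causal
    modelling engine with variational-Laplace inversion, enumeration of
    structured model spaces over default-mode-network regions with hippocampal
    inclusion patterns, fixed-effects Bayesian model selection with family
    inference, Bayesian model and parameter averaging, cross-subject stability
    analysis, and Fisher-z functional connectivity with FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
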