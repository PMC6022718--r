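Package: ecosig
Title: Signatures of Ecological Processes in Microbial Community Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to determine which ecological processes are compatible with
    an observed microbial community time series. Implements a three-step
    classification scheme: (i) noise-type profiling of per-taxon power spectra
    to detect temporal structure, (ii) a neutral covariance test based on
    constant-volatility transformations of grouped relative abundances, and
    (iii) sparse interaction inference for the Ricker model via forward
    stepwise regression with bagging (LIMITS), with one-step-ahead prediction
    and goodness-of-fit scoring. Bundles community simulators
    (Dirichlet-multinomial sampling, Hubbell neutral drift, a self-organized
    instability model, Ricker and generalized Lotka-Volterra dynamics) and a
    Klemm-Eguiluz interaction-matrix generator with tunable connectance and
    positive-edge percentage, so the whole pipeline is testable without
    external data. Preprocessing utilities (rarefaction, monotone
    interpolation, interval thinning, measurement-noise models) support
    application to real abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
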