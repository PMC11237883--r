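Package: dcmrel
Title: Reliability of Dynamic Causal Models of Resting-State Electrophysiology
Version: 0.1.0
Authors@R:
    person("dcmrel", "maintainers", email = "maintainers@dcmrel.dev",
           role = c("aut", "cre"))
Description: Tools for assessing the test-retest reliability of dynamic
    causal models (DCM) fitted to resting-state cross-spectral densities.
    Implements a conductance-based canonical-microcircuit neural mass model
    (AMPA, GABA and NMDA channels) with a linearised spectral forward model,
    variational-Laplace model inversion with a free-energy bound on log
    model evidence, Bayesian model reduction, parametric empirical Bayes
    (including third-level "PEB of PEBs" contrasts), a compound-symmetry
    covariance-component test of the reliability of model evidences, and
    synthetic-cohort generators so that every stage of the pipeline can be
    exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
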