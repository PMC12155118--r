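Package: basinmirage
Title: When Discrete-State HMMs Invent States: Langevin Dynamics,
    Measurement Models, and State-Count Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates single-molecule time series as overdamped Langevin
    dynamics in one-dimensional effective potentials, corrupts them with a
    boxcar-binned Gaussian readout model, and analyzes the results with
    discrete-state hidden Markov models: maximum-likelihood (Baum-Welch)
    fits at fixed state counts, BIC state-number selection, and a Bayesian
    nonparametric HMM with Beta-Bernoulli state loads sampled by Markov
    chain Monte Carlo. Provides scripted experiments demonstrating how the
    inferred number of states tracks the acquisition scheme (binning,
    readout noise) and the potential geometry rather than the number of
    physical basins, together with two continuous generalizations: the
    hidden Markov jump process (continuous time) and Gaussian-process
    reconstruction of the potential from trajectory drift (continuous
    space).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
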