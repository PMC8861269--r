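Package: activeforage
Title: Active Inference Simulation of Goal-Directed Spatial Foraging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete state-space active inference agents for goal-directed
    navigation and epistemic foraging on a grid world. Implements a partially
    observable Markov decision process generative model with Dirichlet priors
    over likelihood and transition mappings, variational belief updating by
    gradient descent on free energy, expected-free-energy planning over
    enumerated policies with risk, ambiguity and novelty components,
    precision (inverse-temperature) dynamics over policies, and concentration
    parameter learning. Simulated neurophysiological readouts (firing-rate
    rasters, local field potentials, dopamine traces, theta-band filtering
    and time-frequency maps) are derived from the belief-updating traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
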