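Package: semiflex
Title: Replica-Exchange Monte Carlo and Microcanonical Analysis of
    Flexible and Semiflexible Bead-Spring Polymers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained simulation and statistical analysis of flexible
    and semiflexible polymers. A bead-spring chain with truncated-shifted
    12-6 Lennard-Jones interactions, FENE bonds and a cosine bending
    potential is sampled by replica-exchange (parallel tempering) Metropolis
    Monte Carlo with displacement and pivot updates and adaptive step-size
    calibration; simulated annealing is provided for ground-state search.
    Per-temperature energy histograms are combined into a density-of-states
    estimate by multiple-histogram reweighting (WHAM), from which canonical
    observables (mean energy, heat capacity, structural fluctuations) and
    the microcanonical entropy are computed. Phase transitions are located
    and classified with the generalized microcanonical inflection-point
    method using Bezier (Bernstein) smoothing with analytic derivatives.
    Structural characterization of low-energy conformations includes the
    squared radius of gyration, pair distributions, contact maps and
    secondary-structure streak detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
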