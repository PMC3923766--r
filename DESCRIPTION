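Package: segsim
Title: Stochastic Simulation of Damage Segregation in Homeostatic Cell
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of irreversible damage accumulation in a
    homeostatic tissue of somatic cells, with symmetric or asymmetric
    partitioning of newly acquired damage between daughter cells, in well-mixed
    or one-dimensional ring topologies. Includes the deterministic mean-field
    hierarchy for the well-mixed system with its closed-form Poisson steady
    state, first-passage (collapse-time) experiments and parameter sweeps, and
    an exact Markov-chain oracle for validating the engine on tiny instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
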