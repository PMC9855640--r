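Package: crusim
Title: Stochastic Calcium-Release-Unit Simulation of Cardiac
    Excitation-Contraction Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A compartmental, stochastic whole-cell simulator of rat
    ventricular myocyte excitation-contraction coupling. Calcium release
    units containing Markov-gated L-type calcium channels and ryanodine
    receptor clusters are simulated with per-site random-number streams and
    an adaptive explicit-Euler timestep. Calmodulin variants that weaken
    calcium-dependent inactivation of the L-type channel are expressed as a
    multiplicative reduction of the open-to-inactivated transition rate,
    derived from the variant's calcium-binding affinity. Includes calcium
    spark detection and summary statistics, action-potential-duration and
    alternans metrics, Welch t-test comparisons, pacing and beta-adrenergic
    protocols, and a driver that reruns the variant-by-frequency experiment
    grid at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ggplot2,
    optparse
Config/testthat/edition: 3
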