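Package: phenomem
Title: Multi-Compartment Phenotypic Memory in Microbial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of phenotypic memory in microbial
    populations modelled as a linear chain of 'on' compartments attached to
    a single 'off' state. Provides the compartment rate matrix with full
    spectral analysis and closed-form equilibria, exact deterministic
    propagation by matrix exponentials (including piecewise-constant
    environment schedules), an exact Gillespie stochastic simulator with a
    specialized single-cell residence-time sampler, gamma maximum-likelihood
    fitting and exponentiality tests for residence times, and a
    fluctuating-environment (antibiotic treatment) fitness protocol that
    compares memory lineages against equilibrium-calibrated memoryless
    switchers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    deSolve,
    pracma,
    jsonlite
Config/testthat/edition: 3
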