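Package: assemblytime
Title: Time Complexity of Stochastic Self-Assembly Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact stochastic (Gillespie) simulation of nucleation-and-growth
    self-assembly of heterogeneous target structures: N copies of S distinct
    monomer species assemble into 1D rings, 2D sheets or 3D cubes by
    dimerization, single-monomer attachment and Arrhenius detachment. The
    package implements four canonical control scenarios (reversible binding,
    dimerization control, activation/influx control and just-in-sequence
    supply with onion-shell protocols and nonstoichiometric ramps), a
    species-symmetric Becker-Doring mean-field integrator for 1D
    cross-checks, and an experiment layer that measures minimal assembly
    times T90, locates optimal control parameters and extracts time
    complexity exponents (theta) and control parameter exponents (phi) from
    log-log power-law fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    igraph,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
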