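Package: warburgsim
Title: Spread of a Warburg-Like Overflow Phenotype in a Nutrient-Coupled Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the early spread of an aberrant cell phenotype with
    Warburg-like overflow metabolism through a healthy tissue coupled to a
    blood reservoir. Provides a stochastic lattice model (nutrient and waste
    reaction-diffusion with Michaelis-Menten uptake, waste-shuttle coupling
    between aberrant and healthy cells, and Gillespie birth/death dynamics of
    aberrant cells), a spatially homogeneous mean-field reduction with
    quasi-steady-state metabolite levels, closed-form substrate and
    aberrant-fraction thresholds with phase-region classification, and
    experiment drivers for phase sweeps, bistability scans and shuttle
    knockouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
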