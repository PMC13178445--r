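Package: caliberflow
Title: Caliber-Force Design of Nonequilibrium Markov Jump Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing and designing molecular-machine networks modeled
    as ergodic Markov jump processes on multigraphs. Computes steady-state
    observables (state probabilities, edge traffics, net and cycle fluxes, entropy
    production), the conjugate caliber forces for node dwelling, edge exchange and
    cycle completion (including the non-invertible catalytic extension), analytic
    flux-routing response rules for node-energy and kinetic-barrier perturbations,
    and canonical-coordinate transforms for inverse design. Includes application
    models for the F1-ATPase rotary motor with the Equal Traffic Principle bound,
    kinetic proofreading with speed/error/cost design paths and barrier
    classification, and Michaelis-Menten enzyme inhibition with dead-end and
    leaky-loop analysis, plus a seeded random-network sampler for validation
    ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    MASS,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
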