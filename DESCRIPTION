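Package: dynFBA
Title: Dynamic Genome-Scale Flux Balance Analysis of Glucose-Limited Yeast
    Cultivations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples genome-scale (and toy) stoichiometric metabolic models to
    bioreactor mass balances for glucose-limited aerobic batch and fed-batch
    cultures. The metabolic block solves a bi-objective quadratic program
    trading growth-rate maximisation against total squared flux, with MOMA
    (minimisation of metabolic adjustment) for gene-knockout simulation. The
    kinetic block maps culture state to exchange-flux constraints
    (Michaelis-Menten glucose uptake, minimum secretion/consumption rates,
    maintenance ATP); the dynamic block integrates volume, biomass, glucose
    and by-product balances with exponential feed profiles. Includes seeded
    global calibration of kinetic parameters, Fisher-information-based
    sensitivity/identifiability/significance diagnostics with iterative
    reparametrization, goodness-of-fit scoring, knockout screening and
    feeding-policy evaluation, plus generators for toy networks and synthetic
    cultivation datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    quadprog,
    deSolve,
    DEoptim,
    nloptr,
    nortest,
    xml2,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
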