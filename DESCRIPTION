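Package: dnastack
Title: Rule-Based Kinetic Simulation of a DNA Stack Data Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a last-in first-out (LIFO) stack data structure
    implemented with polymerising DNA hybridisation and toehold-mediated
    strand-displacement chemistry on streptavidin beads. Stack operations
    (record, pop) are compiled to staged add/wait/wash protocols and executed
    either with the Gillespie direct stochastic simulation algorithm
    (just-in-time reaction enumeration, compiled core) or with deterministic
    mass-action kinetics on a truncated polymer species set. Includes the
    imperfect-washing carry-over model (bead-loss fraction mu, supernatant
    transfer fraction phi0), the pop-limit performance statistic, parameter
    sweeps (washing, concentration/wait-time, pipetting noise), gel
    band-pattern prediction, and calibration of washing parameters from
    ranked band orderings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
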