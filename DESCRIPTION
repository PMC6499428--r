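Package: cardiotherm
Title: Coupled Heat-Bidomain Simulation of Cardiac Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-dimensional simulator of cardiac electrical activity coupled to
    tissue heat transfer. Solves the bidomain (or reduced monodomain) equations
    with temperature-scaled Mitchell-Schaeffer and Aliev-Panfilov ionic kinetics,
    coupled to Pennes' bioheat equation with Joule self-heating from the
    propagating action potential, on uniform structured grids with a fully
    implicit BDF2 (Gear) time integrator and Newton iteration. Includes
    declarative experiment protocols (planar-wave temperature sweeps, S1-S2
    spiral initiation, regional cooling and global hypothermia schedules) and
    measurement utilities for action potential duration, rise time, conduction
    velocity, Q10 temperature coefficients, spiral-tip tracking and Joule
    heat-accumulation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
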