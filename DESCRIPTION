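Package: cardioloop
Title: Cycle-to-Cycle Fluid-Structure Coupling for Cardiac Chambers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulator for sequential (cycle-to-cycle) coupling of
    cardiac wall mechanics and intraventricular blood flow on an idealized
    two-dimensional left-ventricle geometry. Provides transversely isotropic
    (Guccione) and Neo-Hookean passive material laws with a periodic
    double-Hill activation driver, a reduced radial wall-mechanics stage
    closed by a lumped diode/Windkessel circulation, an incompressible ALE
    finite-volume flow solver on a boundary-fitted moving grid with a
    Darcy-Forchheimer porous valve model and passive-scalar washout tracking,
    and the mean-free spatially resolved pressure-factor exchange that feeds
    the fluid wall-pressure field back into the mechanics stage. Includes
    Euclidean-distance convergence diagnostics, pressure-volume loops,
    residual-volume traces, and CSV/VTK exchange formats for running the
    stages stand-alone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
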