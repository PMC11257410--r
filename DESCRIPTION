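Package: oxsplit2d
Title: Multiscale Finite-Volume/Green's-Function Solver for Tissue Oxygen
    Transport Around Microvessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves steady oxygen diffusion with Michaelis-Menten consumption in
    two-dimensional brain tissue containing circular vascular sources. The
    concentration field is split into a slowly varying part, discretised by a
    two-point flux finite-volume scheme on a coarse cartesian grid, and a
    rapidly varying part captured analytically by localized single-layer
    (logarithmic) potentials around each vessel. Includes sub-grid
    reconstruction of the concentration field, a boundary-collocation resolved
    reference solver, a well-mixed coarse-grid baseline and the Peaceman well
    model, error benchmarking utilities, and seeded generators for random
    capillary beds and periarteriolar oxygen-gradient studies across cortical
    layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
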