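Package: gvshell
Title: Geometry and Pseudo-Atomic Modelling of Gas Vesicle Shells
Version: 0.1.0
Authors@R:
    person("gvshell", "developers", email = "gvshell@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the protein shell of bacterial gas
    vesicles. Builds complete pseudo-atomic vesicle models from a single
    GvpA-like monomer by placing copies on a parametric cylinder-plus-cone
    helix, applying landmark-pivot correction rotations and duplicating by
    the two-fold (D1) axis. Also provides the associated helical-geometry
    calculus (rise/twist conversions, polymorph diameter ladders, arc
    lengths), simulated 2D projections with width-profile and layer-line
    analysis, a grid-based widest-path estimate of pore bottleneck
    diameters, and sigmoid fitting of collapse-pressure curves with
    bootstrap uncertainty. A synthetic-data module generates toy monomers,
    collapse curves, projection images and pore scenes with known ground
    truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
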