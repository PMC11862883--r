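Package: monosurf
Title: Langmuir Monolayer and Coarse-Grained Monolayer Analysis for
    Drug-Lung-Surfactant Interaction Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studies of inhaled-drug interaction with
    lung surfactant monolayers. Covers surface pressure-area isotherm
    analysis (compression modulus, Davies-Rideal phase classification,
    lift-off and collapse detection, constant-pressure relaxation metrics),
    surface-potential isotherms (apparent dipole moment, critical-area
    detection), composition and dosing arithmetic (mole-to-mass fractions,
    drug molecule counts for a target weight concentration, dose-to-molecule
    conversion, box/area-per-lipid geometry), and coarse-grained monolayer
    trajectory analysis (second-Legendre chain order parameters, surface
    tension from the pressure tensor, radial distribution functions with
    minimum-image periodicity, drug aggregation clustering, pore detection,
    collapse detection, density profiles, and roughness). Synthetic-data
    generators with attached ground truth make every analysis testable
    without molecular dynamics runs or instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
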