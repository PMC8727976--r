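Package: ventsplitr
Title: Lumped-Parameter Simulation of Ventilator Splitters and 3D-Printed Flow Restrictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale tools for differential multi-patient ventilation with a
    Y-splitter and small-bore orifice restrictors. Simulates pressure-controlled
    inspiration into two patient branches through a lumped resistance-compliance
    (RC) model of the airway, lung and breathing circuit, coupled to nonlinear
    quadratic restrictor pressure-flow laws. Includes orifice hydraulics
    (Reynolds number, discharge-coefficient pressure drop, fourth-power diameter
    sensitivity), least-squares fitting of pressure-flow coefficients and their
    cross-diameter power laws, titration of inspiratory time to a target
    end-inspiratory volume, analysis of 3D-print dimensional tolerance (wall
    undersizing and layer-ridge roughness via Fourier feature extraction), and
    synthetic bench-measurement generators with instrument-grade noise so every
    stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
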