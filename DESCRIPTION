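Package: gliderstab
Title: Static Stability, Control Effectiveness and Glide Performance from
    Wind-Tunnel Force-Balance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces six-axis wind-tunnel force-balance recordings of
    scale glider models to nondimensional aerodynamic coefficients,
    estimates static stability derivatives by per-replicate central
    differences over angle sweeps, locates and classifies trim points,
    quantifies control effectiveness of appendage deflections (including
    control reversal and roll/yaw function shifts across angle of
    attack), and computes equilibrium-glide and comparative maneuvering
    metrics at full scale.  Ships a seeded quasi-steady flat-plate
    glider simulator that emulates the wind-tunnel acquisition (sensor
    frame, mounting misalignment, sensor noise) so the entire pipeline
    is testable against analytically known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
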