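Package: exotendon
Title: Simulation-Guided Design of Exotendon Springs for Running
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A planar muscle-driven simulation framework for predicting the
    energetic effect of an exotendon (a passive extension spring connecting
    a runner's shoes) on the metabolic cost of running, together with the
    experimental analysis pipeline used to evaluate candidate designs.
    Includes a 20-coordinate planar skeletal model with Hill-type
    muscle-tendon units and smoothed Hunt-Crossley foot-ground contact, an
    inverse-dynamics-based tracking optimization over half a gait cycle
    with left-right symmetry, a stiffness by slack-length design sweep with
    stride-duration selection, indirect-calorimetry processing (Brockway
    equation, standing-baseline subtraction, respiratory-exchange-ratio
    exclusion), marker-derived spring tension estimation, paired
    statistical workflows with Bonferroni correction, and synthetic-data
    generators for every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
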