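Package: pdivsim
Title: Probabilistic Cell-Size Homeostasis: Simulation and Inference
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of fission-yeast cell-size control under
    five division rules (sizer, adder, timer, size-dependent division
    probability, and cyclin-threshold accumulation), estimation of the
    size-to-division dose-response (Hill curve) from single-cell septation
    snapshots, Fantes-plot and coefficient-of-variation homeostasis metrics
    with parameter sweeps over the Hill parameters, and a cyclin-threshold
    analysis of dividing versus division-blocked cytometry tables. Includes
    synthetic single-cell data generators so every analysis stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
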