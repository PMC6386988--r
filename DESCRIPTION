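Package: telepalp
Title: Simulated Tele-Palpation with Neuromorphic Tactile Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully software-simulated tele-palpation workbench: a virtual
    silicone phantom with stiffer hemispherical inclusions, gesture-driven
    cartesian-stage control with a neutral-sphere dead zone, spike-based
    encoding of contact force through a regular-spiking Izhikevich neuron
    integrated at 5 kHz, a configurable virtual subject that presses a key
    on perceived firing-rate changes, and the downstream psychophysical
    analyses (true/false-positive classification under spatial tolerances,
    per-material identification rates, and logistic-CDF psychometric fits
    yielding perceptual stiffness thresholds). Includes the apparatus
    characterization protocols: indentation-based stiffness estimation and
    trajectory-tracking error via enclosed boundary areas.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
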