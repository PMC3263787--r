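Package: neonirs
Title: Probe-Design Simulation and Trial Power Analysis for Neonatal
    Cerebral Near-Infrared Spectroscopy Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and evaluation of near-infrared spectroscopy
    (NIRS) cerebral oximeter probe designs for the preterm newborn brain,
    together with power and sample-size analysis for a randomized trial of
    cerebral oximetry. Provides a weighted-packet Monte Carlo photon
    transport engine for layered semi-infinite tissue (diffuse reflectance
    and per-layer partial pathlengths at arbitrary source-detector
    separations), a closed-form diffusion-approximation reflectance model
    used as an independent cross-check, the spatially-resolved-spectroscopy
    (SRS) tissue oxygen saturation estimator, an experiment harness that
    sweeps brain and skin/scalp oxygen saturation across candidate probe
    geometries to quantify responsiveness, bias and robustness, and
    analytic plus simulation-based sample-size calculators for continuous
    and binary trial endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
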