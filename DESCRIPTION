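Package: strainwave
Title: Strain-Dependent Conduction Velocity Remodeling in Ventricular
    Monodomain Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monodomain reaction-diffusion simulation of human ventricular
    electrophysiology with a phenomenological link between myofiber strain
    amplitude and transverse conduction velocity. Provides an idealized
    truncated-ellipsoid left-ventricle geometry with rule-based fibers,
    infarct core and border-zone labeling, the Ten Tusscher-Panfilov (2006)
    human ventricular myocyte model with border-zone and transmural-layer
    conductance remodeling, conductivity calibration against conduction
    velocity targets, a virtual S1-S2 stress test with vulnerable-window
    scanning and ventricular-tachycardia detection, and repolarization-
    gradient substrate metrics.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
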