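Package: vocbend
Title: Shape Tracking and Calibration for Chemo-Mechanical VOC Sensor Films
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chemo-mechanically bending polymer sensor
    films exposed to volatile organic compound (VOC) headspaces. Provides a
    synthetic-data generator that emulates randomized headspace exposure
    sessions (hysteretic multi-exponential tip-angle dynamics, rendered binary
    filament image sequences, emulated manual annotations), a computer-vision
    midline tracker with tip-angle extraction, shape-ensemble principal
    component analysis, multi-start triple-exponential transient fitting, and
    forward and inverse linear calibration between film bending and acetone or
    ethanol exposure, with hysteresis diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
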