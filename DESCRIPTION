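Package: phantomtwin
Title: Digital Twin of an LCD-Based Dynamic Phantom for Pulse Oximeter Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale software replica of a light-guided dynamic tissue
    phantom used to validate photoplethysmography (PPG) instruments and pulse
    oximeters. The package models the liquid-crystal-display (LCD) modulated
    optical channel of such a phantom, implements the characterization
    pipeline that sweeps the LCD drive voltage to find the functional range
    and build a normalized lookup table, maps target PPG waveforms to
    modulation-voltage traces (with modulation-depth scaling and DAC
    quantization), and closes the loop with a pulse-oximetry estimator:
    trough-to-trough pulse segmentation, the per-pulse R ratio of ratios,
    window averaging, and the empirical linear SpO2 calibration. Scripted,
    seeded heart-rate and oxygen-saturation case studies reproduce the
    closed-loop validation experiments entirely in software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
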