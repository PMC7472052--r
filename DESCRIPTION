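Package: stripescope
Title: Tilted-Sensor Stripe Tracking for Longitudinal Tissue Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models, simulates and analyses a compact image-based displacement
    sensor in which an image sensor tilted 45 degrees to the optical axis of a
    wide-field fluorescence microscope converts specimen depth into the column
    position of an in-focus stripe. Provides a paraxial ray-transfer (ABCD)
    model of the two-lens relay, a seeded synthetic frame renderer, an FFT
    Gaussian annular bandpass filter for baseline-drift removal, per-row
    peak-value stripe localization, linear displacement calibration with
    indication-error reporting, and amplitude/frequency analysis of motion
    traces.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
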