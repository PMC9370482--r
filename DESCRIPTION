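Package: mechanoindent
Title: Single-Cell Microindentation Mechanosensitivity Assay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the calcium-imaging readout of single-cell
    microindentation mechanosensitivity assays on a stepper-driven probe
    stage. Provides stage-calibration metrology (bidirectional systematic
    error, backlash estimation and integer-step overshoot correction,
    bidirectional positioning accuracy, total positioning uncertainty),
    digital-holography phase-to-thickness morphometry, construction and
    G-code emission of progressive indentation trains, ratiometric fura-2
    trace normalization with activation-transient and membrane-rupture
    detection, activation-rate statistics with threshold sweeps, and seeded
    synthetic-data generators emulating every input so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
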