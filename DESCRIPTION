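Package: flagellabeat
Title: Flagellar Beat Quantification and Waveform Alignment for Tethered Sperm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the flagellar beat of head-tethered sperm recorded in
    dark-field video microscopy. Segments each frame, traces the flagellum by
    skeletonization, monitors the angle between the head-to-midflagellum line
    and the cell's symmetry axis, and estimates per-frame beat frequency by
    sliding-window sinusoid fitting with event-aware window placement. Builds
    "stop-motion" waveform envelopes by head registration, annulus-based neck
    azimuth measurement and rotational alignment, and normalizes fluorescence
    traces as percent dF/F0 for plate-reader and stopped-flow conventions. A
    synthetic video and trace generator with full ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
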