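Package: lfaforge
Title: Design, Scheduling and Image Quantification for Automated Lateral
    Flow Assay Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running large lateral flow assay (LFA) development
    experiments on a multi-channel liquid handling robot.  Enumerates
    factorial screens of capture/detection antibodies, sample matrices and
    reagent concentrations; plans working solutions and serial dilutions
    from stock solutions by volume/mass balance; expands timed assay
    protocols into channel-batched pipetting worklists scheduled under
    per-strip timing constraints and validates them with a discrete-event
    simulator; quantifies test-line signal from strip images by
    width-averaged densitometry with flank-median baseline subtraction;
    and summarises antibody-pair screens (blank subtraction, heatmaps,
    cross-reactivity ranking, signal-to-noise metrics).  A seeded
    synthetic-data module generates strip images and screen tables with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
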