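Package: neuropilseg
Title: Two-Stage Neuropil Segmentation and Bilateral Morphometry for 3D
    Fluorescence Brain Stacks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A detection-led segmentation workflow for 3D confocal-style
    image stacks of insect brains. Stage one locates neuropil regions of
    interest on 2D Z-projections with a trainable single-stage detector
    evaluated by mean average precision and a coverage-success criterion.
    Stage two segments the neuropil inside each region with a compact 3D
    encoder-decoder trained under a composite loss combining weighted Dice
    loss and categorical focal loss.  Downstream morphometry filters
    segmented cohorts by connected-component structure and quantifies
    bilateral (left/right) volume asymmetry.  A synthetic phantom generator
    with known masks, boxes, midline and controllable asymmetry makes the
    whole pipeline trainable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
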