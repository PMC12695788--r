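Package: berrydetr
Title: Multi-Domain Enhanced Detection Transformer for Small-Fruit Detection and Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Re-implementation of a multi-domain enhanced real-time detection
    transformer (MDE-DETR) for small-target fruit detection and counting in
    cluttered orchard imagery. Provides the enhanced feature-extraction backbone
    (EFENet) with reparameterized convolutions, the multi-domain feature-fusion
    neck (MDFFN) combining space-to-depth lossless downsampling, omnidirectional
    large-kernel blocks and frequency-domain attention, the adaptive deformable
    downsampling module (ADSample), assembly of the full detector and its
    RT-DETR-style baseline with analytic parameter and FLOP accounting, a dataset
    pipeline (splitting, offline augmentation, YOLO/COCO annotation I/O, a
    synthetic orchard-scene generator), COCO-style detection metrics, and the
    detection-to-counting regression analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
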