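Package: cropseg
Title: Crop-Type Mapping from Single-Date Multispectral Imagery with an
    Attention U-Net and Point Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-level crop-type classification of single-date 4-band
    (red, green, blue, near-infrared) satellite rasters. Implements a
    five-level encoder-decoder segmentation network with multi-stage
    efficient channel attention (ECA), PReLU activations, a Dice plus
    cross-entropy compound loss with ignore-value masking, and a
    point-refinement branch that re-classifies the hardest pixels from
    mid-level encoder features. Includes the full dataset-preparation
    protocol (rectangular masking, sliding-window tiling, masked-fraction
    filtering, seeded 8:1:1 splits), a synthetic parcel-scene generator,
    confusion-matrix metrics (OA, AA, mIoU), a training engine with early
    stopping and repeated-random-split cross-validation, and an ablation
    switchboard. The network forward/backward passes and Adam optimizer
    are implemented on dense linear algebra via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    class,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
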