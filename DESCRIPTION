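Package: veinfuse
Title: Dual-Branch Appearance and Venation Classification of Leaf Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying plant species from leaf photographs by
    combining two complementary cues: overall appearance (colour, texture,
    shape) and vein morphology. Includes a classical image-processing
    pipeline that converts an RGB leaf photo into a clean binary vein map
    (Otsu segmentation, CLAHE, homomorphic illumination correction, an
    oriented Gabor filter bank, unsharp masking and adaptive thresholding),
    a fused-image constructor that embeds the vein map in the red channel,
    class-frequency-aware augmentation and class weighting for imbalanced
    datasets, a two-stream convolutional classifier with late feature-level
    fusion, standard evaluation reports, and a procedural synthetic-leaf
    generator with ground-truth vein masks so the whole pipeline can be
    exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
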