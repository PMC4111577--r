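Package: mslcv
Title: Multi-Scale Shape-Constrained Localized Active Contour Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Level-set segmentation of low-contrast, speckle-degraded 2-D
    ultrasound-like images. Implements the global Chan-Vese region energy,
    its localized (ball-neighbourhood) variant, a shape-constraint force
    that pulls the evolving contour towards an initial ellipse outside a
    configurable zero narrow band, and a two-stage Gaussian-pyramid
    coarse-to-fine driver (MSLCV). Includes Dice and mean-sum-of-square
    contour-distance evaluation metrics, a seeded speckle-phantom
    generator for testing, and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    yaml,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
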