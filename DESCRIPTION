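Package: mofex
Title: Motion Feature Extraction, Tracking and Injury Classification from Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing human-motion image sequences: per-pixel
    Gaussian-mixture background modelling and foreground extraction, central
    and normalized image moments, kernel-histogram CAMSHIFT colour tracking
    with red-marker feedback, snake-energy contour localization,
    eigen-subspace nearest-neighbour injury classification, and graph
    convolutional propagation of per-detection features. Includes a seeded
    synthetic-scene generator with full ground truth (masks, trajectories,
    marker centroids, class labels) and an end-to-end batch pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
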