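Package: gradseg
Title: Automatic Thresholding from Gradients at Region Boundaries
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automatic threshold segmentation of single-channel greyscale
    micrographs by maximising the image gradient along the boundary of the
    thresholded phase. Provides the global variant (exhaustive search over
    grey levels for the threshold whose phase boundary carries the largest
    total or average gradient, with multi-threshold detection from local
    maxima of the gradient curve) and the region-based adaptive variant
    (per-component boundary scoring across all levels, maximum projection of
    the labelled boundary stack, regional maxima and binary fill), including
    shape-constrained object specification (circularity and size bounds),
    object-matched Jaccard evaluation against gold-standard masks, a
    deterministic synthetic nuclei-scene generator with ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, tiff, png, jsonlite, optparse
Suggests: testthat (>= 3.0.0), EBImage
biocViews: Software, CellBiology, Segmentation, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
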