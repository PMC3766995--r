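Package: minkograde
Title: Minkowski-Functional Texture Analysis and Symbolic Classification of
    AFM Tissue Height Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for grading tissue texture from atomic force microscopy
    (AFM) height maps. Height maps are flattened by a first-order plane fit,
    rank-equalized to 256 gray levels, and thresholded at every level into a
    stack of binary level sets. For each level the three 2-D Minkowski
    functionals (covered area, boundary length, Euler characteristic) are
    computed, giving three 256-point curves per image. The Euler and contour
    curves are reduced to 15 geometric descriptors (extrema, zero crossing,
    steepness, areas, width, centroid) which feed a strongly typed
    genetic-programming symbolic classifier with stratified cross-validation.
    A synthetic tissue-texture generator emulating fibrous low-grade and
    cavity-riddled high-grade morphologies supports end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
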