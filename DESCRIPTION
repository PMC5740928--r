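Package: ffirst
Title: Fast Features Invariant to Rotation and Scale of Texture
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-scale rotation-invariant texture description and
    classification for biological image analysis (tree bark patches and
    segmented leaf scans). Implements sign- and magnitude local binary
    patterns on a Gaussian scale stack, histogram Fourier rotation
    invariants over the full set of binary-pattern orbits (with optional
    extra invariants from first Fourier coefficients of adjacent orbits),
    segmentation-aware interior/border description, an explicit feature
    map of the histogram-intersection kernel, and a dual coordinate
    ascent linear one-vs-all support vector machine with Platt
    probability calibration. Includes a deterministic synthetic fixture
    generator for textures and leaf-like objects, evaluation metrics
    (mean reciprocal rank, top-k accuracy), and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
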