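Package: fmlp
Title: Fuzzy Multilayer Perceptron and Skin Lesion Border Irregularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a fuzzy multilayer perceptron (F-MLP) for binary
    classification in which gradient-descent weight updates are scaled by a
    per-layer ambiguity factor derived from fuzzy c-means memberships, and the
    activation is a type-II fuzzy sigmoid pair (lower and upper envelopes of
    the ordinary sigmoid). Includes the full skin lesion border-irregularity
    pipeline the classifier was designed for: a histogram-driven fuzzy edge
    filter for border detection on grayscale images, box-counting fractal
    dimension and convex-hull convexity as the two-value irregularity measure,
    a synthetic generator of regular and irregular lesion masks, and an
    evaluation harness (ratio splits, confusion matrices, sensitivity,
    specificity, ROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    pROC,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
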