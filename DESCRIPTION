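Package: retiseg
Title: Retinal Blood-Vessel Segmentation by Hybrid Thresholding,
    Classification and Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments blood vessels in retinal fundus photographs with a
    hybrid pipeline: background normalization and adaptive local
    thresholding extract well-contrasted large vessels; the residual
    binary fragments are classified into thin-vessel segments versus
    noise by a radial-basis support vector machine with asymmetric class
    costs, using a 12-dimensional per-pixel feature vector built from
    oriented line detectors applied to the gray image and to undecimated
    Haar wavelet and curvelet-style modulus images; classified thin
    segments are then grown from their endpoints by Hessian-gated
    tracking to recover the full vascular network.  A synthetic fundus
    phantom generator with exact ground truth makes every stage testable
    without external image databases; the DRIVE directory layout is
    supported as an optional input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    png,
    tiff,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
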