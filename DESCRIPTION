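Package: ihcseg
Title: Boundary-Aware Multi-Scale Segmentation of Invasive Carcinoma in
    Breast IHC Images with Mask-Conditioned Ki-67 Quantification
Version: 0.1.0
Authors@R:
    person("ihcseg", "developers", email = "ihcseg@example.org",
           role = c("aut", "cre"))
Description: Tools for segmenting ductal carcinoma in situ (DCIS) and
    invasive carcinoma (IC) regions in immunohistochemistry (IHC) image
    tiles and whole-slide-like images, and for the downstream Ki-67
    proliferation-index quantification that the segmentation masks enable.
    Implements a three-branch boundary-attention segmentation network
    trained in two stages: a semi-supervised stage combining supervised
    boundary-aware losses with weak/strong consistency regularisation on
    unlabeled tiles, and a multi-scale stage that fuses corner, center and
    downscaled context predictions through attentional feature fusion with
    the backbone frozen. Includes a procedural generator of IHC-like
    synthetic tiles and pseudo whole-slide images with exact nucleus-level
    ground truth, stain color deconvolution, nucleus detection, per-class
    intersection-over-union evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    digest,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
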