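Package: lodgeseg
Title: Compact Attention-Augmented Semantic Segmentation for Crop Lodging Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping crop lodging in aerial field imagery with
    compact encoder-decoder convolutional segmentation networks. Provides a
    global spatial-attention block built on query-key-value affinities that
    can be inserted into small convolutional backbones, channel-wise
    knowledge distillation with a temperature softmax for training small
    student networks from larger teachers, atrous (dilated) convolutions with
    spatial pyramid pooling, receptive-field and cost profilers, a synthetic
    lodged-field mosaic generator with an exact index-mask ground truth, the
    tiling and region-split protocol used for large orthomosaics, and
    confusion-matrix / mean-intersection-over-union evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
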