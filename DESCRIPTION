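Package: retvasc
Title: Retinal Vasculature Analysis for Dementia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A modular pipeline for classifying Alzheimer's disease from
    retinal fundus vasculature: ensemble image-quality gating with a
    unanimous-vote rule, multiscale vesselness segmentation, exact
    age/sex/eye matched control-group construction, per-pixel Welch t-test
    feature selection feeding a nested cross-validated RBF support vector
    machine, and multi-scale occlusion-sensitivity saliency maps. Ships a
    synthetic vascular-tree and fundus generator so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    nnet,
    png,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
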