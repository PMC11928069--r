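Package: ecganet
Title: Spatial-Attention Image Networks for Cardiac-Arrest Risk from 12-Lead ECG Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting emergency-department cardiac arrest from raster
    images of printed 12-lead ECG reports. Provides a synthetic report generator
    with analytic ground-truth pixel masks (grid, trace, lead-label glyphs,
    ST-segment windows), an image-cleanup chain (blur/threshold binarization,
    connected-component label removal, morphological opening, histogram
    equalization and rebinarization), a ResNet-style convolutional classifier
    with CBAM-style spatial-attention gates after each residual stage, a
    recall-weighted binary cross-entropy (binary recall loss) with analytic
    gradients, Grad-CAM saliency maps, confusion-matrix and ranking metrics
    (AUROC/AUPRC), and a training/evaluation/ablation pipeline with class-ratio
    resampling. All components run at desk scale on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    EBImage,
    png,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
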