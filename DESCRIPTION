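Package: jigsawmam
Title: Jigsaw-Puzzle Self-Supervised Pretraining for Mammographic
    Breast Cancer Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, desk-scale pipeline for studying jigsaw-puzzle
    self-supervised pretraining on mammographic crops: a seeded synthetic
    mammogram-phantom generator with lesion masks and patient-grouped
    manifests, study-style image selection and 512x512 cropping rules,
    maximal-Hamming permutation-set construction for the 3x3 gapped puzzle
    pretext task, a shared-weight context-free network and a binary
    cancer classifier built on a compact CNN engine, patient-grouped
    repeated cross-validation with ROC/AUC, Youden operating points,
    subgroup metrics and paired AUC comparisons, and Grad-CAM attention
    maps for the fine-tuned classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    tiff,
    jsonlite,
    withr,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
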