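Package: shufflecerv
Title: Attention-Augmented ShuffleNet Classifiers for Cervical Lesion Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lightweight convolutional networks for five-class cervical-lesion
    image classification: ShuffleNet-style inverted residual units built from
    channel split, channel shuffle and depthwise separable convolution,
    optionally fused with Squeeze-and-Excitation (SE) or Selective-Kernel (SK)
    channel attention.  Includes an analytic convolution-cost model
    (multiplication counts, parameters, serialized size), a directory-of-images
    data pipeline with stratified 90/10 splitting and standard augmentation, a
    seeded synthetic colposcopy-like image generator, an SGD-Nesterov training
    loop, and a multiclass evaluation suite (confusion matrices, precision,
    recall, F1, one-vs-rest ROC AUC, repeated-run summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    jpeg,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
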