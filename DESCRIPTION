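Package: oncosgan
Title: Semi-Supervised Generative Adversarial Networks for Oncogenic Variant
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies somatic variants as oncogenic or benign from tabular
    annotation features using a semi-supervised generative adversarial
    network (SGAN).  A discriminator with two class logits doubles as a
    real-versus-synthetic critic through the K+1-class softmax identity
    D(x) = Z(x)/(Z(x)+1), so large unlabeled variant pools sharpen the
    decision boundary learned from a small labeled set.  Includes the full
    feature pipeline (missingness filtering, k-nearest-neighbour imputation,
    noise-dithered one-hot encoding of discrete clinical evidence scores,
    min-max scaling), alternating adversarial training with feature
    matching, interpretation-score inference, an eight-metric evaluation
    panel (accuracy, precision, sensitivity, specificity, F1, MCC, ROC-AUC,
    PR-AUC), a synthetic-data generator emulating the assumed mixed
    discrete/continuous feature structure, and scripted experiments
    (label-budget sweeps, feature-group ablations, supervised-only
    baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
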