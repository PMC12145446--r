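Package: organoidvit
Title: Spatiotemporal Vision Transformer Classification of Organoid
    Brightfield Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies brightfield organoid z-stack time series into three
    drug-induced liver injury (DILI) concern classes with a three-stage
    image-spatial-temporal encoder: a ViT image encoder over 16x16 patches,
    a two-layer ViT spatial encoder over focal planes, a bidirectional LSTM
    over imaging days, and an MLP head. Includes a synthetic organoid
    phenotype simulator (hollow-sphere growth, growth arrest,
    disintegration), masked-image-modeling corruption, K-fold
    cross-validation training with AdamW, one-vs-rest evaluation metrics and
    ROC/AUC, Laplacian-variance focus stacking, temporal and spatial
    ablation experiments, and attention-rollout heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
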