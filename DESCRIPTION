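Package: stormdistill
Title: Knowledge Distillation for Dense-Emitter STORM Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, training and evaluation pipeline for studying
    knowledge distillation between convolutional networks that reconstruct
    super-resolved single-molecule localization microscopy (STORM) images
    from dense-emitter diffraction-limited frames. Provides a ThunderSTORM
    style synthetic frame simulator (Poisson shot noise, Gaussian point
    spread function, uniform background), sparse-reconstruction losses
    (L1L2, Attentive Imitation Loss with teacher-error normalization, hint
    mean squared error), factorized teacher (encoder-decoder with input
    skip connection) and student (SRCNN) architectures split at a
    32-channel hint layer, seeded Adam training with plateau learning-rate
    scheduling, NMSE/SSIM evaluation, and hint-layer representation
    analysis (pooled features, 2-D embeddings, pairwise distances).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
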