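Package: colonyGAN
Title: GAN-Based Dataset Augmentation and Temporal Classification for
    Stem-Cell Colony Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for patch-based analysis of grayscale stem-cell colony
    microscopy: morphological colony segmentation (blur, local-entropy
    filtering, opening, Otsu thresholding, hole filling, small-object
    removal), 64x64 patch datasets with stratified cross-validation folds,
    class-wise generative adversarial networks (dcGAN, entropy-regularized
    dcGAN, wGAN, auxiliary GAN, Metropolis-Hastings selection) trained with
    a compact built-in convolutional network engine, image-entropy
    distribution metrics (Shannon entropy, histogram overlap, entropy MSE),
    generated-image quality control (inception score, Frechet inception
    distance, optimal-epoch selection), and a temporally constrained
    three-stage hierarchical classifier whose class imbalances are corrected
    with generated images. Includes a deterministic synthetic-fixture
    generator emulating the four colony morphologies (debris, dense, spread,
    differentiated) so the full pipeline is testable without proprietary
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    nnet,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
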