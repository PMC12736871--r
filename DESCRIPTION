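Package: femseg
Title: Frequency-Domain Feature Enhancement for Ultrasound Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for breast-ultrasound lesion segmentation built around a
    frequency-domain feature enhancement module (FEM): half-spectrum Fourier
    decomposition of deep convolutional features into low/mid/high bands,
    band-wise refinement, cross-band fusion and residual injection. Provides
    encoder-decoder segmentation networks (U-Net, U-Net++, DeepLabV3 and the
    frequency-augmented FADeepLabV3) on a small pure-R automatic
    differentiation engine, the full Dice/IoU/pixel-accuracy/AUC and
    focal-loss metric suite, a synthetic speckle-noise ultrasound phantom
    generator with BUSI-style directory output, and a class-imbalance-aware
    training pipeline with stratified splitting, weighted sampling, plateau
    learning-rate scheduling, early stopping, checkpointing and pruned
    random hyperparameter search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
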