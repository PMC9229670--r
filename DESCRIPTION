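Package: vesselgan
Title: Conditional Adversarial Networks for Cerebrovascular Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting blood vessels in time-of-flight magnetic
    resonance angiography (TOF-MRA) slice stacks with a conditional generative
    adversarial network whose generator concatenates a U-Net with a residual
    U-Net. Provides synthetic tubular-vessel phantoms with exact ground-truth
    masks, region-of-interest preprocessing (intensity thresholding plus
    morphological closure, resizing, CLAHE contrast enhancement), mirror-flip
    and patch-zoom data augmentation, the dual U-Net generator and PatchGAN
    discriminator with full training machinery (combined adversarial + L1
    generator objective, binary cross-entropy discriminator objective, Adam
    and RMSProp optimizers), confusion-count evaluation metrics (Dice,
    precision, sensitivity, specificity), and a k-fold cross-validation
    protocol over volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    RNifti,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Depends:
    R (>= 4.0)
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
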