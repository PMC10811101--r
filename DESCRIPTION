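Package: spikeglume
Title: Segmentation and Glume-Pubescence Classification of Wheat Spike Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated image-analysis pipeline for scoring glume pubescence
    (haired vs. hairless glumes) in laboratory photographs of single wheat
    spikes. The pipeline segments each scene into background, color-reference
    target, spike body and awns with a compact convolutional network applied
    over overlapping tiles whose per-class weights are averaged per pixel;
    extracts background-blacked spike-body crops at several scales; stratifies
    species-grouped, class-imbalanced image sets into train/validation/test
    subsamples that preserve the hairless-to-haired ratio k; trains a binary
    pubescence classifier evaluated by ACC, precision, F1 and ROC-AUC with
    Grad-CAM activation maps; and quantifies robustness of the classifier to
    box blur and brightness distortions and to image magnification. A synthetic
    spike "phantom" generator with pixel-exact ground-truth masks makes every
    stage trainable and testable without a wheat image collection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
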