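Package: echoGAN
Title: Cycle-Consistent Adversarial Enhancement of B-Mode Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enhancement of low-quality B-mode ultrasound images by
    cycle-consistent adversarial translation between a low-quality and a
    high-quality imaging domain. Implements dual UNet generators and dual
    spectrally normalized PatchGAN discriminators trained with adversarial,
    cycle-consistency, paired L1 and perceptual (deep feature distance)
    losses under a conditional label-smoothing rule for the discriminators;
    a four-metric full-reference evaluation suite (structural similarity,
    locally normalized cross-correlation, peak signal-to-noise ratio and a
    learned-perceptual-style feature distance) with paired one-sided
    Wilcoxon comparison; and a synthetic speckle-phantom generator that
    produces paired low/high-quality images so the whole
    train/enhance/evaluate loop runs without external data. Network
    training is performed by a compact reverse-mode differentiation engine
    with compiled im2col/col2im convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, png, tiff, yaml, jsonlite, withr,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: ImageProcessing, Visualization
RoxygenNote: 7.3.3
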