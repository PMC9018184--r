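Package: occlurec
Title: Occlusal Surface Reconstruction with a Dual-Discriminator
    Adversarial Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs the missing occlusal (chewing) surface of a
    prepared mandibular molar from depth-map renderings of dental scans.
    Provides a reversible pixel-distance depth encoding of 3D tooth
    surfaces with entropy-guided contrast selection, pose standardization
    of tooth meshes, a seeded parametric generator of synthetic molar
    scenes (preparation, adjacent teeth, opposing jaw, occlusal
    fingerprint and groove masks, inter-jaw gap field), an
    encoder-decoder completion network with a multi-rate dilated
    convolution bottleneck, dual global/local adversarial discriminators
    with a staged training schedule, depth-map to mesh back-projection,
    and image (PSNR, SSIM, FSIM) and surface-deviation (SD, RMS) quality
    metrics. All training and inference run on the CPU with a small
    deterministic convolution engine built on 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
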