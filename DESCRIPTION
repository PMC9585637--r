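Package: dlads
Title: Deep-Learning-Guided Dynamic Sparse Sampling for Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dynamic sparse sampling for mass spectrometry imaging (MSI).
    Iteratively predicts molecularly informative pixel and line-segment
    locations from partial measurements using an estimated
    reduction-in-distortion (ERD) convolutional model, reconstructs
    multi-channel ion images from sparse samples by inverse-distance-weighted
    interpolation, and quantifies throughput gains and reconstruction
    fidelity (PSNR, MSE, cosine similarity). Includes a synthetic tissue
    phantom generator, pointwise and segment-linewise selection policies
    with Otsu thresholding, closed-loop simulation against fully measured
    data, a file-based mock acquisition handshake, and an imzML importer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
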