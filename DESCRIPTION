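Package: equitomo
Title: Self-Supervised Equivariant Denoising and Missing-Wedge Correction
    for Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Restores cryo-electron tomograms from pairs of independently
    noisy filtered-backprojection reconstructions, without clean training
    data. Implements the missing-wedge Fourier projector and its rotated
    variants, the 40-element group of interpolation-free rotations and
    flips, a Noise2Noise data-fidelity loss, an equivariance loss with
    plug-in targets and double network application, training of a compact
    3D convolutional network with hand-derived gradients and the Adam
    optimizer, patch-based inference with partition-of-unity blending,
    Fourier shell correlation evaluation, a tilt-series simulator with
    dose and angle splitting, and MRC volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
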