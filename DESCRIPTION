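Package: tomowedge
Title: Self-Supervised Missing-Wedge Compensation and Denoising for
    Cryo-Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An iterative, self-supervised pipeline that restores
    missing-wedge information and denoises cryo-electron tomograms.
    Subtomograms extracted from the tomograms themselves are rotated and
    re-corrupted with an additional missing wedge to form training pairs
    for a volumetric U-net; after each training round the network's
    predictions are merged back into the originals in Fourier space so
    that measured information is never modified.  Includes deterministic
    preprocessing (Wiener-filter CTF deconvolution under an empirical
    spectral signal-to-noise model, statistical mask generation),
    reconstruction-consistent noise simulation by filtered backprojection
    of 2D Gaussian images, overlap-tile whole-tomogram prediction,
    gold-standard radial/conical/3D Fourier shell correlation with
    resolution readout, MRC2014 and STAR file input/output, and a
    synthetic phantom benchmark for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
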