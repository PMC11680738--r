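Package: ztegap
Title: Dead-Time Gap Infilling for Zero Echo Time Radial MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for the dead-time gap in
    zero echo time (ZTE) radial magnetic resonance imaging. Generates
    center-out radial trajectories (2D and 3D phyllotaxis), synthetic
    multi-coil phantom acquisitions with SNR-calibrated complex Gaussian
    noise, and recovers the missing central k-space samples with five
    methods: the algebraic pair-line solver, the Stoch-Olejniczak real-part
    variant, ZINFANDEL kernel extrapolation, conjugate-gradient SENSE, and
    structured low-rank iterative infilling (Hankel lifting, singular value
    thresholding and data-consistency projection). Includes a Kaiser-Bessel
    gridding non-uniform FFT, center-of-k-space regridding, squared-error and
    SNR metrics, and Monte Carlo sweeps over gap size and noise level.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
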