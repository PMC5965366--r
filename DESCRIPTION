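Package: dose4d
Title: Real-Time 4D Dose Reconstruction for MLC-Tracked Lung SBRT on a
    Synthetic Breathing Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of online four-dimensional dose
    reconstruction for multileaf-collimator (MLC) tracked lung stereotactic
    body radiotherapy. Builds a ten-phase synthetic breathing phantom with
    analytic deformation fields, fits respiratory ellipses and generates 25 Hz
    tumour trajectories with online phase binning, precomputes per-phase
    sparse dose-influence data from an analytic pencil-beam kernel, replays
    static, untracked and tracked step-and-shoot deliveries, accumulates dose
    onto the peak-exhale reference phase by energy-mass transfer, and
    evaluates DVH endpoints (GTV D98, lung V20, cord and airways D2) for
    ITV, midventilation and moving-target-volume margin strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
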