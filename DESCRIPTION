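Package: balloonassim
Title: Balloon-Model Data Assimilation for BOLD fMRI with
    Angiography-Calibrated Blood Volume Fraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Model-based analysis of BOLD fMRI time series built on the
    Balloon hemodynamic model.  Provides a deterministic forward simulator
    for the four-state hemodynamic system and its nonlinear BOLD observation
    equation, calibration of the per-voxel resting blood volume fraction
    (V0) from a co-registered high-resolution angiography volume by
    threshold segmentation and subvoxel counting, joint estimation of hidden
    physiological states and model parameters from noisy BOLD series with an
    unscented Kalman filter, a two-region dynamic causal model driven by the
    same assimilation engine, and a synthetic-data generator (block-design
    stimuli, noisy BOLD datasets with known ground truth, vessel phantoms
    with exactly known vessel fractions) so that the whole pipeline is
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
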