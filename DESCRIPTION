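Package: meningealCSD
Title: Analysis of Meningeal Afferent Calcium Imaging Around Cortical Spreading Depolarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-photon calcium imaging of meningeal
    afferent fibers recorded in awake head-fixed mice around a cortical
    spreading depolarization (CSD) episode. Provides a validated session
    container (ROI and neuropil fluorescence, wheel position, per-frame
    affine registration and Z-shift series, binned background fluorescence),
    neuropil correction and rolling-percentile baselining, threshold-based
    fluorescence event detection, hidden-Markov locomotion segmentation,
    meningeal deformation series from affine parameters, event-correlation
    fiber clustering, CSD calcium-wave onset mapping with speed and
    direction estimation, ongoing-activity change classification, lagged
    elastic-net encoding models with sensitization classification, and a
    synthetic-session generator with known ground truth for parameter
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    rhdf5,
    glmnet,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
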