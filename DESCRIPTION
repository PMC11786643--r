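Package: ecimage
Title: Directed Effective Connectivity Images from Multichannel EEG-ECG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates directed (effective) connectivity between simultaneously
    recorded EEG and ECG channels with three multivariate-autoregressive (MVAR)
    estimators: pairwise Granger causality, partial directed coherence (PDC) and
    the directed transfer function (DTF). Recordings are filtered, decimated,
    common-average re-referenced and segmented into stationary windows; a joint
    MVAR model is fitted per window (AIC order selection; stability, residual
    whiteness and consistency diagnostics), band-averaged 35x35 coupling
    matrices are rendered as colour raster images, and emotional states are
    classified from those images with a cross-validated, pluggable image
    classifier. Ships a synthetic-data module generating stable ground-truth
    MVAR systems and 4-class EEG-ECG-like datasets so the whole pipeline is
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
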