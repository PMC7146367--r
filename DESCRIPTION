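Package: emgconfound
Title: Simulating and Evaluating Limb-Position and Contraction-Intensity
    Confounds in Myoelectric Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how limb position and contraction intensity
    confound surface-EMG pattern recognition. Provides a seeded synthetic
    multi-channel EMG generator whose statistical structure carries the two
    confounds (position-dependent channel re-mixing and stabilization
    baseline activity; intensity-dependent amplitude gain, low-frequency
    spectral-peak shift and Gaussian/Laplacian amplitude mixing), the
    standard conditioning chain (notch, band-pass, decimation, overlapping
    window segmentation), a catalog of time-domain features and the named
    feature sets built from them (TD, TDAR, TSTD, LSF4, LSF9, TDPSD,
    Hjorth), five classifiers under four cross-validation frameworks
    (intra-condition, inter-condition, single-vs-all, multi-vs-all) with
    leave-one-trial-out evaluation, and the total error rate, active error
    rate and Davies-Bouldin separability statistics used to quantify the
    degradation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    jsonlite,
    randomForest,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    class,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
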