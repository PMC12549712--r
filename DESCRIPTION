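Package: atlaspd
Title: Transformer-LSTM Staging of Early Parkinson's Disease from fNIRS Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, classification and interpretation of
    block-design functional near-infrared spectroscopy (fNIRS) recordings for
    three-class staging of early Parkinson's disease (healthy controls versus
    Hoehn-Yahr stages 1 and 2). Provides a seeded generator of dual-wavelength
    optical recordings with a canonical double-gamma haemodynamic response and
    group-dependent prefrontal activation; a full signal chain (optical density,
    temporal derivative distribution repair, hybrid spline/wavelet motion
    correction, scalp coupling and signal quality gating, zero-phase Butterworth
    filtering, modified Beer-Lambert inversion, baseline correction,
    Savitzky-Golay smoothing, outlier handling, chained-ridge multiple
    imputation and channel-wise standardisation); an attention-based
    Transformer-LSTM classifier (ATLAS-PD) with a stacked-LSTM and four
    classical baselines; evaluation utilities (stratified splits and folds,
    bootstrap confidence intervals, McNemar tests, Gaussian-noise robustness
    curves, ANOVA power analysis and standardised effect sizes); and an
    interpretability layer (permutation channel importance with anatomical
    region aggregation, and t-SNE embedding of penultimate-layer features).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    ranger,
    kernlab,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
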