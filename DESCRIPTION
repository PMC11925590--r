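Package: ftirdx
Title: Digital Spectral Biomarker Panels from ATR-FTIR Plasma Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building peak-anchored spectral biomarker panels and
    diagnostic classifiers from attenuated-total-reflectance Fourier-transform
    infrared (ATR-FTIR) plasma spectra. Provides spectra containers and CSV /
    JCAMP-DX input, Savitzky-Golay derivative preprocessing, deterministic
    Kennard-Stone sample-set partitioning, Relief-F feature ranking, an
    iterative sensitivity/specificity-targeted marker search, matching of
    selected wavenumbers to purified-protein absorption peaks, a six-model
    classifier comparison harness with ROC/AUC and paired DeLong tests,
    biomarker-analyte association statistics, and a synthetic-cohort generator
    with planted band-depth effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    nnet,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    signal,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
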