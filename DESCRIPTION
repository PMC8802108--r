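Package: cardiobeat
Title: Beat Detection, Arrhythmia Scoring and Calcium Kinetics for In Vitro Cardiomyocyte Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for functional recordings of spontaneously
    beating cardiomyocyte preparations: R/S peak detection and contraction
    metrics from atomic-force-microscopy mechanocardiograms, multichannel
    field-potential beat analysis with channel quality control, cutoff-based
    arrhythmic-event scoring with Yates-corrected contingency testing and
    Poincare return maps, calcium transient and spark kinetics from line-scan
    fluorescence, and the heteroscedasticity-robust group-comparison layer
    (Welch and Brown-Forsythe ANOVA, Games-Howell, Kruskal-Wallis, robust
    outlier screening, dose-trend regression). A phenomenological signal
    simulator with full ground truth emulates drug-induced chronotropic,
    inotropic and stochastic arrhythmogenic effects so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
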