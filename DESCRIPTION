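Package: nirsleep
Title: Neonatal Sleep Staging from High-Frequency Near-Infrared Spectroscopy
Version: 0.1.0
Authors@R:
    person("nirsleep", "developers", email = "nirsleep@example.org", role = c("aut", "cre"))
Description: Tools for classifying active versus quiet sleep in preterm
    infants from a single high-frequency (100 Hz) near-infrared spectroscopy
    (NIRS) sensor. Converts raw dual-wavelength light intensities to
    hemoglobin concentration changes via the modified Beer-Lambert law,
    rates signal quality on a 1-5 scale, extracts heart rate and respiratory
    rate by windowed spectral peak picking within adaptive frequency bands,
    assembles eight 1 Hz feature modalities per one-minute epoch, and trains
    a 1-D convolutional neural network alongside six benchmark classifiers
    (KNN, kernel Naive Bayes, linear SVM, random forest, AdaBoost and
    gradient-boosted trees) with inverse-frequency class weighting.
    Includes pooled and leave-measurement-out cross-validation, vitals
    agreement statistics (mean error, RMSE, Bland-Altman limits of
    agreement, Pearson correlation), a postmenstrual-age sensitivity
    analysis, and a fully seeded synthetic neonatal NIRS simulator so the
    whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    matrixStats,
    quadprog,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5
Config/testthat/edition: 3
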