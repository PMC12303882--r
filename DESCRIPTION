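Package: eegdem
Title: EEG Relative Band Power Features and a TCN-LSTM Classifier for
    Dementia Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying Alzheimer's disease,
    frontotemporal dementia and healthy controls from resting-state EEG.
    Implements modified relative band power feature extraction over six
    frequency bands (Welch power spectral density, 6 s epochs with 50%
    overlap, channel averaging), EEG preprocessing (zero-phase Butterworth
    bandpass, windowed artifact-subspace correction, ICA component
    removal), a lightweight hybrid temporal-convolutional-network plus
    LSTM classifier trained with Adam, SMOTE class balancing, stratified
    splits and k-fold cross-validation, a full evaluation suite
    (confusion matrices, per-class precision/recall/F1/specificity,
    one-vs-rest ROC/AUC), and exact Shapley-value feature attributions
    with global-importance, beeswarm and heatmap reports. Includes a
    synthetic EEG generator with class-conditional band-power profiles,
    and readers/writers for EDF, EEGLAB .set and feature-matrix CSV
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
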