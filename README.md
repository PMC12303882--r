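# eegdem

Classification of Alzheimer's disease (AD), frontotemporal dementia
(FTD) and healthy controls (HC) from resting-state EEG, with
explanations. The package is aimed at researchers in EEG-based
neurodegeneration screening who want a self-contained, fully tested R
implementation of the whole chain: preprocessing, spectral feature
engineering, a lightweight deep classifier, evaluation, and
Shapley-value explanations — plus a synthetic EEG generator so
everything runs and is testable without any data download.

## What it computes

**Features.** Recordings are cut into 6 s epochs with 50% overlap. Per
epoch and channel, Welch's method (2 s Hann segments, 50% overlap)
estimates the power spectral density, and the relative band power of
band *b* is

    RBP_b = sum of PSD over bins in b / sum of PSD over 0.5-45 Hz

over six bands — Delta [0.5,4), Theta [4,8), Alpha [8,16), Zaeta
[16,24), Beta [24,30), Gamma [30,45] — averaged over channels
(unweighted mean of per-channel RBP). The modified scheme's Zaeta band
splits the classical high-alpha/low-beta range; the classical five-band
scheme is available for comparison. The six fractions of every epoch
sum to 1.

**Classifier.** `tcn_lstm()` fits a hybrid temporal-convolutional +
LSTM network: two residual blocks of causal 1-D convolutions (32
filters, kernel 7, batch normalization, spatial dropout, kernel-1
residual projections) → 64-unit LSTM → dense 128/192/256 → softmax.
With 6 features and 3 classes: 131,587 parameters (131,331 trainable,
256 non-trainable). Training uses Adam (lr 1e-4, batch 32), categorical
cross-entropy and early stopping; forward pass, backpropagation and the
optimizer are implemented in R and verified by a finite-difference
gradient check.

**Preprocessing.** Zero-phase order-4 Butterworth bandpass 0.5–45 Hz
(second-order-section cascade), windowed artifact correction (0.5 s
windows flagged above 17 robust SDs and reconstructed from the clean
principal subspace), and seeded FastICA component removal with a
frontal-correlation auto mode.

**Evaluation and explanation.** One-vs-rest precision / recall / F1 /
specificity, confusion matrices, trapezoid ROC/AUC (equal to the
rank-sum statistic), stratified splits, SMOTE balancing, k-fold
cross-validation, and exact Shapley-value attributions (full coalition
enumeration over the ≤6 features — local accuracy holds exactly) with
global-importance, beeswarm and heatmap reports.

## Worked example

Simulate a labelled three-class dataset, extract features, train,
evaluate, explain:

```r
library(eegdem)

profiles <- unname(default_profiles())          # AD / FTD / HC spectra
ds <- generate_eeg_dataset(profiles, n_per_class = 8, duration = 60,
                           seed = 42)           # 19 ch @ 500 Hz
fm <- extract_features(ds)
fm
#> rbp_features: 456 epochs x 6 bands (Delta, Theta, Alpha, Zaeta, Beta, Gamma);
#>   classes: AD=152, FTD=152, HC=152

sp <- split_features(fm, 0.8, 0.1, 0.1, seed = 42)
mm <- fit_minmax(sp$train)
fit <- tcn_lstm(
  apply_minmax(sp$train, mm)$values, sp$train$labels,
  control = train_control(max_epochs = 60, seed = 42),
  validation = list(x = apply_minmax(sp$val, mm)$values, y = sp$val$labels)
)
fit
#> TCN-LSTM classifier
#>   input length 6, classes: AD, FTD, HC
#>   parameters: 131,587 total (131,331 trainable, 256 non-trainable)
#>   trained 60 epochs; final loss 0.0027, accuracy 1.000 (val 1.000)

te <- apply_minmax(sp$test, mm)
probs <- predict(fit, te$values)
metrics_from_confusion(
  confusion(te$labels, fit$class_order[max.col(probs)], fit$class_order)
)
#> Accuracy: 1.0000
#>  class precision recall f1 sensitivity specificity support
#>     AD         1      1  1           1           1      15
#>    FTD         1      1  1           1           1      15
#>     HC         1      1  1           1           1      15
```

The three synthetic classes are fully separable by construction, so the
held-out metrics are perfect; the interesting part is *why* the model
decides as it does:

```r
bg <- shap_background(apply_minmax(sp$train, mm)$values, n = 15, seed = 1)
att <- shap_values(fit, te$values[1:12, ], bg)
global_importance(att, "AD")
#>   feature importance
#> 1   Delta 0.33383335
#> 2   Theta 0.23391256
#> 5    Beta 0.18533459
#> 4   Zaeta 0.05957079
#> 3   Alpha 0.03124772
#> 6   Gamma 0.01945558
```

The AD profile is built with raised delta/theta and suppressed beta —
the importance ranking recovers exactly the bands that define the class.
`plot_importance()`, `plot_beeswarm()` and `plot_heatmap()` render the
standard report figures; `run_pipeline("config.yaml")` drives the whole
chain (simulate/ingest → preprocess → features → prep → train → evaluate
→ explain) from a validated YAML config and writes all artifacts plus a
reproducibility manifest. A thin command-line wrapper lives at
`inst/cli/eegdem.R`.

Real recordings are read with `read_eeg()` (EDF, or EEGLAB `.set` saved
without MAT compression, including `.fdt` payloads).

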