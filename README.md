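# atlaspd

Three-class staging of early Parkinson's disease (healthy controls vs
Hoehn–Yahr stages 1 and 2) from 22-channel prefrontal fNIRS recorded under a
block-design fine-motor task. The package is aimed at methods researchers in
fNIRS-based classification: because the underlying clinical recordings are
not publicly deposited, it pairs every stage of the analysis with a seeded
synthetic-data generator so the whole chain is runnable, testable and
reproducible end to end.

It provides:

* **Simulation** — `simulate_cohort()` builds balanced cohorts of
  dual-wavelength (695/830 nm) optical recordings under the 840 s paradigm
  (10 s pre-task + 7 × [30 s rest / 30 s task / 50 s rest] + 60 s rest,
  100 Hz): a double-gamma haemodynamic response (peak ~5.5 s, undershoot
  ~15 s) convolved with the task boxcar, class-dependent frontal-polar
  amplitudes and latencies, cardiac/respiratory/Mayer oscillations, drift,
  motion transients, bad channels and missing samples, forward-projected
  through the modified Beer–Lambert law.
* **Preprocessing** — `build_dataset()` runs optical density → TDDR motion
  repair → hybrid spline/wavelet correction → SQI/SCI channel gating
  (thresholds 2.5 / 0.5) → zero-phase 0.1 Hz Butterworth → Beer–Lambert
  inversion (DPF 6.0, 3 cm) → pre-task baseline correction →
  Savitzky–Golay smoothing → decimation → IQR winsorisation →
  chained-ridge multiple imputation → channel-wise Z-scoring, into an
  `N × 22 × T` tensor with full provenance.
* **Models** — `atlas_pd()` fits the hybrid attention classifier (input
  projection → batch norm → positional encoding → Transformer encoder →
  LSTM → softmax; the engine, including backpropagation, is implemented in
  the package and gradient-checked in the tests); `lstm_net()` fits the
  stacked-LSTM baseline; `fit_baseline()` fits SVM / random forest / kNN /
  BP-network comparators with their fixed hyperparameters;
  `bayes_search()` runs Gaussian-process hyperparameter optimisation with
  Expected Improvement.
* **Evaluation** — `evaluate_classifier()` (confusion matrix, macro
  metrics, one-vs-rest AUC, bootstrap CIs), `mcnemar_test()`,
  `noise_robustness()` (accuracy under additive Gaussian noise,
  σ = 0–0.5, summarised by the normalised area `AUC_robustness`),
  `anova_power()` / `anova_sample_size()` / `cohens_d()` /
  `cohens_f_from_eta2()`.
* **Interpretability** — `permutation_importance()` with
  `aggregate_by_region()` over the anatomical montage, and
  `embed_features()` (t-SNE of penultimate-layer features).

## The model in brief

A session is a multichannel time series `X ∈ R^{22×T}`. After the signal
chain, the hybrid classifier computes

    H0 = BN(X'W_in) + PE            (projection, batch norm, positional code)
    Hl = EncoderLayer_l(H{l-1})     (multi-head self-attention + FFN, l = 1..L)
    h  = mean_t LSTM(HL)_t          (temporal-mean readout)
    p  = softmax(W_out h)

trained with Adam on cross-entropy + L2 (λ = 0.001), dropout 0.3/0.4, early
stopping on validation loss (patience 20) and checkpointing on validation
accuracy. Defaults follow the tuned protocol (2 encoder layers, 4 heads,
d_model 128, learning rate 8e-4). Sample-size and effect-size utilities use
the noncentral F distribution with noncentrality `f²N`.

## Worked example

Simulate a cohort with a strong frontal-polar effect gap, preprocess it to
1 Hz, train a compact hybrid model and evaluate it on a freshly simulated
test cohort:

```r
library(atlaspd)

design  <- block_design(sampling_hz = 10)    # the 840 s paradigm at 10 Hz
effects <- group_effect_profile(             # stage-dependent activation
  fpc_amplitude_uM = c(HC = 0.4, HY1 = 1.0, HY2 = 0.15),
  nonfpc_fraction  = c(HC = 0.3, HY1 = 0.8, HY2 = 0.3),
  latency_s = c(HC = 0, HY1 = 0, HY2 = 4), variability = 0.10)
cohort <- simulate_cohort(15, design = design, effects = effects, seed = 1)
cohort
#> fNIRS cohort: 45 subjects (15/15/15), task pegboard, 22 channels, 840 s @ 10 Hz

ds <- build_dataset(cohort, chromophore = "hbo", target_hz = 1)
ds
#> fNIRS dataset: 45 x 22 x 840 (hbo, 1 Hz), z-scored
#>   labels: HC=15 HY1=15 HY2=15
#>   chain: od -> tddr -> motion_hybrid -> quality -> butter -> mbll ->
#>          baseline -> savgol -> decimate_1hz -> iqr -> impute -> zscore

sp   <- split_dataset(ds$labels, fractions = c(0.85, 0, 0.15), seed = 42)
spec <- model_spec("atlas", d_model = 16, n_heads = 2,
                   n_transformer_layers = 1, lstm_hidden = 16,
                   learning_rate = 2e-3, epochs = 45, batch_size = 8)
fit <- atlas_pd(ds$data[sp$train, , ], ds$labels[sp$train],
                ds$data[sp$test, , ], ds$labels[sp$test], spec = spec)
fit
#> atlas_pd fit: 2563 parameters, best epoch 22 (val acc 0.833), 45 epochs run

test_cohort <- simulate_cohort(10, design = design, effects = effects, seed = 2)
ds_test <- build_dataset(test_cohort, chromophore = "hbo", target_hz = 1)
evaluate_classifier(fit, ds_test, ds_test$labels, bootstrap_n = 200)
#> Test set: n = 30
#> accuracy 0.667 | macro P 0.670 R 0.667 F1 0.645 | macro AUC 0.890
#> 95% CI accuracy [0.499, 0.833] (bootstrap n=200)
#>     sensitivity specificity precision    f1  auc
#> HC          0.7        0.65     0.500 0.583 0.78
#> HY1         1.0        0.95     0.909 0.952 1.00
#> HY2         0.3        0.90     0.600 0.400 0.89
```

The cohort print shows the balanced design; the dataset print records the
exact chain applied; the fit print reports the checkpointed epoch; the
evaluation reports accuracy, macro metrics and per-class
sensitivity/specificity/AUC with bootstrap CIs on 30 held-out subjects the
model never saw. (This illustration trains on 31 subjects; the test suite
runs the properly powered version with 51 training subjects, where the same
configuration reaches ~0.89 fresh-cohort accuracy.) Power-analysis
utilities are one-liners:

```r
anova_sample_size(f = 0.30, k = 3, alpha = 0.05, power = 0.80)
#> [1] 111
cohens_f_from_eta2(0.205)
#> [1] 0.5078008
```

A thin command-line front end over the same functions lives at
`inst/cli/atlaspd.R` (subcommands `simulate`, `power`, `run-all`), and
`run_pipeline(run_config(...))` executes the whole chain — simulate,
preprocess, split, train both deep models, cross-validate the baselines,
evaluate with bootstrap CIs and McNemar pairings, noise robustness,
permutation importance and t-SNE — writing every artifact (JSON metrics,
CSV curves and tables, the resolved config) to a run directory.

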