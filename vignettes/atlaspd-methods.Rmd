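---
title: "Methods: simulation, preprocessing and classification of block-design fNIRS for Parkinson staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, preprocessing and classification of block-design fNIRS for Parkinson staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`atlaspd` implements a complete analysis chain for three-class staging of
early Parkinson's disease (healthy controls, Hoehn–Yahr stage 1, stage 2)
from 22-channel prefrontal fNIRS recorded under a block-design pegboard
task: a seeded generator of realistic dual-wavelength recordings, the
signal-processing chain from raw intensity to a model-ready tensor, an
attention-based Transformer–LSTM classifier (ATLAS-PD) with a stacked-LSTM
and four classical baselines, evaluation utilities (power analysis, noise
robustness, paired tests, bootstrap intervals), and an interpretability
layer. Because no clinical recordings are distributed, the generator is a
first-class, tested component: it defines the study conditions under which
every empirical claim in the test suite is made.

# The session and montage

A session is 840 s at 100 Hz: a 10 s pre-task window, then seven cycles of
30 s rest, 30 s task, 50 s rest, and a 60 s residual rest. The total
duration and the per-phase durations are fixed by the protocol; the cycle
count is not uniquely determined by them, so `block_design()` treats
`total_s` as authoritative and accepts any cycle structure that fits (the
default, 7 cycles plus a 60 s residual, preserves all printed durations).
The montage is the fixed 22-channel prefrontal layout with its anatomical
partition (L-FPC, R-FPC, mFPC, L-DLPFC, R-DLPFC, BA8) and 3 cm
source–detector separation.

# The generator

Each subject's evoked HbO series per channel is a task boxcar convolved
with a canonical double-gamma haemodynamic response (peak 5.5 s, undershoot
15 s, unit peak; the positive-lobe scale is calibrated numerically so the
*combined* kernel peaks at the requested time). The kernel is normalised by
its maximal cumulative sum so that a sustained block plateaus at the
subject's amplitude, which makes "injected amplitude" well defined for
oracles. Class structure enters through a per-class, per-region amplitude
profile with a latency shift: the defaults encode stage-1 frontal-polar
hyperactivation (0.8 µM versus 0.5 µM in controls) and a weakened, delayed
stage-2 response (0.3 µM, +2 s), with 15% between-subject amplitude
variability. HbR is −1/3 of the evoked HbO (the typical inverse response;
the protocol itself never specifies HbR), and the gait-imagery task reuses
the same design at 60% amplitude.

Nuisance structure follows standard fNIRS phenomenology: cardiac (≈1.1 Hz,
0.08 µM), respiratory (≈0.25 Hz, 0.05 µM) and Mayer-wave (≈0.1 Hz,
0.06 µM) oscillations, random-walk drift (0.01 µM·s^−1/2^), white sensor
noise (0.05 µM), motion transients (0.5/min, exponential decay τ = 1.5 s,
added in optical-density space so the motion-repair stage has realistic
targets), occasional flatlined channels (p = 0.02) and missing samples
(p = 0.001). The pulsatile components are shared in phase between HbO and
HbR because they ride on blood volume — this is what gives the scalp
coupling index its physical meaning. Oscillations above the simulation
Nyquist are dropped. Concentrations are forward-projected to strictly
positive dual-wavelength intensity through the same modified Beer–Lambert
model the preprocessing chain inverts (Gratzer/Cope extinction
coefficients at 695/830 nm, DPF 6.0, baseline intensity 1, so only ratios
matter after the optical-density conversion). Everything derives from one
seed per subject, drawn reproducibly from a cohort master seed; cohorts
are bit-identical across runs.

What the generator does *not* emulate — systemic physiology correlated
with the task, optode-position drift, skin blood flow, subject-specific
HRF shape — bounds what passing tests can say about real data: they
validate the machinery (the chain recovers what was injected; the
classifier finds class structure of the assumed kind), not clinical
performance.

# The preprocessing chain

The chain runs per subject in the narrated order: optical density
(reference = pre-task mean), TDDR motion repair, hybrid spline/wavelet
correction, SQI/SCI channel gating, zero-phase 4th-order Butterworth
low-pass at 0.1 Hz, Beer–Lambert inversion to HbO/HbR/HbT, pre-task
baseline subtraction, Savitzky–Golay smoothing (order 3, window 5),
optional block-mean decimation, IQR winsorisation (k = 1.5), chained-ridge
multiple imputation (m = 5) of missing samples, and channel-wise Z-scoring.
Every step is logged in the dataset's provenance.

Numerical choices worth knowing:

* **Zero-phase filtering.** `filtfilt` as shipped rings badly at series
  boundaries for low cutoffs; all zero-phase filtering here uses
  odd-symmetric reflection padding sized to a few periods of the cutoff.
* **TDDR.** The published parameters ("SD threshold 3.0, amplification
  0.5") do not map onto the canonical robust-reweighting formulation, so
  they are interpreted as (a) the robust-z level beyond which derivative
  samples are corrected at all and (b) the blend weight of that partial
  correction. Strong outliers (2× threshold, beyond chance for Gaussian
  noise) trigger a full repair: the artifact region is grown by hysteresis
  on a smoothed robust-z profile so a transient's whole decay is captured,
  the slow component is linearly interpolated across it, and its
  high-frequency content is silenced. Two guards keep clean physiology
  intact: a band-limitedness pre-check (if the largest second difference is
  under 10% of the largest first difference the series cannot contain
  abrupt artifacts and is returned unchanged — this is what makes the
  noiseless recovery test exact), and an edge region that may never seed a
  repair. The repair is iterated to a fixed point so reapplication is a
  near no-op.
* **Hybrid spline/wavelet correction.** Flagged segments are detrended by
  a smoothing spline anchored at the segment entry, residual structure is
  shrunk by universal-threshold Haar soft-thresholding (the Haar transform
  is implemented in-package), and all samples after the segment are
  re-levelled — this is what converts a step artifact back into a flat
  baseline while leaving unflagged samples untouched.
* **Quality indices.** SCI is the zero-lag correlation of the two
  band-passed (0.5–2.5 Hz), unit-variance wavelength series. SQI is a 1–5
  composite of cardiac-band spectral prominence, flatline fraction and
  spike rate combined additively (0.45/0.35/0.20), calibrated so a
  flatline fails the 2.5 threshold on its own while spikes degrade the
  score gradually. At sampling rates that cannot resolve the cardiac band
  the SCI is reported as unresolved and never excludes a channel.
* **Exclusion bookkeeping.** Channels failing SQI < 2.5 or SCI < 0.5 carry
  no signal through the chain and are never imputation donors; after
  normalisation they are refilled with the cross-subject channel mean so
  the model input width stays fixed, and the exclusion mask rides along
  with the dataset. Subjects failing more than half their channels are
  dropped with a provenance note.
* **Z-scoring.** Constant channels return zeros with a flag rather than
  dividing by zero.

The chain's end-to-end identity is tested by regressing the processed
noiseless output on the expected block response — the standard evoked
amplitude estimator — rather than by task/rest window means, which would
conflate the zero-phase filter's edge smearing with amplitude loss.

# The classifiers

ATLAS-PD is a linear input projection (22 → d_model), batch normalisation,
sinusoidal positional encoding, a stack of post-norm Transformer encoder
layers (multi-head self-attention, 4×d_model feed-forward), one LSTM layer
and a dense softmax head on the last hidden state. The plain baseline is a
stacked LSTM (128, 64) with a dense head. Defaults mirror the tuned
protocol (2 layers, 4 heads, d_model 128, dropout 0.3/0.4, learning rates
8e-4/2e-3, 120 epochs, L2 λ = 0.001, early stopping patience 20,
checkpointing on best validation accuracy). Unstated details were fixed
once: Adam, batch 16, sinusoidal encoding, feed-forward 4×d_model, batch
normalisation right after the input projection, and the hybrid's LSTM
width equal to d_model. The LSTM readout feeding the dense head defaults
to the temporal mean of the hidden states rather than the final state:
the session ends with 110 s of rest, so a last-state readout must carry
all task information across a long task-free tail, which measurably
encourages memorisation over generalisation on synthetic cohorts; the
mean readout aggregates evidence where it occurs (`readout = "last"`
remains available in the spec). The whole engine
(attention, LSTM, batch/layer norm, dropout, Adam, global-norm gradient
clipping at 5) is implemented in-package with hand-derived
backpropagation, verified in the test suite against central differences to
about 1e-7. All randomness flows from two seeds — data order/dropout (42)
and weight initialisation (123); repeated runs are bit-identical.

Classical baselines consume per-subject features (per channel: task mean,
rest mean, task−rest difference, SD, slope; the task window shifted 5 s
for haemodynamic delay — the protocol never states how classical models
saw the data, so this featurisation is this package's explicit choice,
with a flattened-series mode also available). Hyperparameters are fixed:
SVM (RBF, C 0.8, gamma "scale", pairwise-coupled probabilities), random
forest (80 trees, depth 8, min node 8), kNN (k 7, inverse-distance
weights, implemented directly since no installed kNN offers distance
weighting with probabilities), and a two-hidden-layer (80, 40)
back-propagation network trained with the package's own Adam (single
hidden-layer implementations could not express it). Feature scaling is fit
on training data only.

Hyperparameter search uses a Gaussian-process surrogate
(`kernlab::gausspr`, RBF kernel, predictive SD enabled) with Expected
Improvement over the stated space (layers 1–5, heads 1–12, learning rate
1e-5–1e-2 log-scaled, width 64–512, dropout 0.1–0.6); head/width
divisibility is enforced by rejection, the learning rate is encoded on its
log scale, and iterations fall back to random sampling (flagged in the
trace) if the surrogate fit fails.

# Evaluation and interpretability

Evaluation reports the confusion matrix, accuracy, macro
precision/recall/F1, per-class sensitivity/specificity, one-vs-rest AUC by
the midrank Mann–Whitney formula (cross-checked against an independent ROC
implementation in the tests), macro AUC as the unweighted mean, and
percentile-bootstrap 95% CIs over test-subject resamples. McNemar's test
uses the continuity-corrected statistic with an exact binomial branch when
the discordant count is below 25. Noise robustness adds N(0, σ²) to the
normalised inputs on the grid σ = 0–0.5, averages accuracy over seeded
repetitions (20 by default; the σ = 0 point is the clean accuracy,
computed without a draw), and summarises the curve by its trapezoidal area
normalised by the σ range, so a constant-accuracy model scores its own
accuracy — the normalisation is this package's convention since the
quantity is named but not defined. Power analysis uses the noncentral F
distribution (λ = f²N) directly; the minimum-N search walks N upward until
the target power is reached.

Permutation importance shuffles one channel's series across subjects
(repeats = 10), takes the mean accuracy drop, min-max normalises to [0, 1]
(an all-equal degenerate case returns zeros with a flag), and ranks with
stable ties by channel id; region scores are arithmetic means of member
channels. How the original analysis permuted is unstated; across-subject
permutation was chosen because it preserves each channel's marginal
distribution. The embedding layer applies exact t-SNE (perplexity
bisection, early exaggeration, momentum descent — implemented in-package;
no t-SNE package is available in the dependency set) to the penultimate
LSTM state.

# Problem sizes used by the test suite

The suite must establish its claims on a desk-scale budget, so the
synthetic study conditions are fixed as follows. The learnability cohort
has 60 subjects (20 per class), simulated at 10 Hz (which keeps cardiac
content below Nyquist for the quality indices) and decimated to 1 Hz
model input (840 steps); the hybrid classifier fitted on it is a compact
member of the family (d_model 16, 2 heads, 1 encoder layer, LSTM 16,
dropout 0.3/0.4, learning rate 2e-3, batch 8, up to 45 epochs) — the
full-width clinical configuration is unnecessary at 60 subjects and would
dominate runtime without changing what the test shows. Its accuracy is
measured on a freshly simulated, disjoint-seed 45-subject cohort from the
same conditions: a 9-subject within-cohort test split would make any
fixed accuracy threshold a coin flip, whereas fresh-cohort evaluation
measures true generalisation with usable power. The learnability profile
uses a deliberately strong frontal-polar effect gap (0.4/1.0/0.15 µM, a
4 s stage-2 delay, stage-1 compensatory recruitment of extra prefrontal
territory, 10% variability): per-channel Z-scoring is scale-invariant, so
class separation must survive normalisation through effective SNR,
latency and spatial extent rather than raw amplitude.

The channel-importance recovery check injects discriminative signal only
into the four frontal-polar channels CH01/CH04/CH05/CH08, with
amplitudes (0.15/0.50/0.03 µM) placed in the *linear* (unsaturated)
post-standardisation regime and 20% shared subject variability so the
four channels carry complementary rather than redundant information —
permutation importance cannot surface a channel whose information is
fully duplicated elsewhere. Importance is computed for the
random-forest comparator driven through the tensor/featurisation
interface on a disjoint-seed evaluation cohort: at this scale the deep
model memorises a 4-channel-confined cohort rather than learning it, and
the importance of a memorising model reflects its memorisation, not the
injected signal (the original interpretability analysis likewise reports
channel importance for every model family, classical ones included). The
deep model's own importance behaviour is property-tested on a learnable
toy. Split-protocol checks (168/36/36, the 204-subject cross-validation
pool) run on a 240-subject cohort simulated at 1 Hz, where simulation is
cheap.

# Known limitations

The generator's class structure is low-dimensional (amplitude, latency,
region pattern); real staging signal is richer and noisier. TDDR's repair
necessarily discards unrecoverable high-frequency content inside artifact
windows, and its partial-correction form slightly shrinks evoked
transitions in noisy data. The SQI components are a reconstruction from
the cited scale's description, not the original algorithm. Training the
full-width model on 84,000-step sequences is infeasible without
decimation; the 0.1 Hz low-pass makes 1 Hz decimation Nyquist-safe, but
the choice of rate (and of HbO as the default chromophore) is
configuration, not a claim about the original analysis.
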