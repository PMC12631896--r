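---
title: "Cross-subject hybrid EEG-fNIRS motor-imagery decoding: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject hybrid EEG-fNIRS motor-imagery decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Motor imagery (MI) modulates two complementary physiological signatures:
an event-related desynchronization (ERD) of the alpha (8-12 Hz) and beta
(12-27 Hz) rhythms over the sensorimotor cortex contralateral to the
imagined hand, visible in EEG within hundreds of milliseconds, and a slower
task-locked hemodynamic response — HbO rising, HbR falling — visible in
fNIRS over seconds. Within-subject decoders work well when a subject shows
strong, typical signatures; stroke patients often do not, and labeled
calibration data from them is scarce. This package decodes a weak *target*
subject by transferring representations learned on a stronger *source*
subject, choosing that source deliberately, and fusing both modalities.

## Pipeline and models

### Preprocessing

EEG: Fourier-domain resampling to a common 200 Hz, zero-phase band-pass
(default 0.5-50 Hz for classification; 0.5-40 Hz is conventional for
time-frequency inspection and is just an argument), epoching over the task
window, and subtraction of each channel's mean over the 3 s pre-stimulus
interval. fNIRS: modified Beer-Lambert inversion of two-wavelength optical
density into HbO/HbR concentration changes, 0.01-0.1 Hz band-pass, the same
epoching and baseline rule. Two non-obvious choices:

* **FFT filtering with raised-cosine transitions** rather than IIR/FIR
  design: it is exactly linear and zero-phase (no ERD-latency distortion),
  needs no filter-design dependency, and makes the linearity property
  testable to machine precision. The record is reflection-padded to tame
  circular wrap-around.
* **Trial window excludes the 2 s cue** (task onset to task onset + 10 s);
  `include_cue = TRUE` restores the alternative, since the boundary is a
  genuine ambiguity.

### Base networks

Both modality networks share the same three-block shape (full conv, full
conv, depthwise separable conv; each with batch normalization and sigmoid;
average pooling after blocks two and three; flatten; a single linear layer
to two logits), with `F1 = 16` first-stage filters and `F2 = 64`. Sigmoid
activations are retained even though ELU/ReLU is more common in EEG CNNs —
the architecture is treated as given, not re-designed. Two printed lengths
of the fNIRS branch are mutually inconsistent with the plain convolution
arithmetic; we reconcile them as (i) a one-sample crop after the first
convolution (101 to 100) and (ii) adaptive average pooling to length 17 in
the second pooling stage, which is what "adaptive average pooling" computes
and reproduces the printed flatten length `64 x 17`. A
`strict_formula = TRUE` spec keeps the uncorrected arithmetic (flatten
`64 x 12`) for comparison.

No deep-learning framework exists in the target environment, so
convolution, batch normalization, pooling, Adam and backpropagation are
implemented directly on R arrays. This is deliberate: the networks and
losses are the scientific content here, and every gradient path is checked
against central finite differences in the test suite (worst relative error
around 1e-6).

### Source selection

A subject's value as a source is its decoding skill times its typicality.
Skill is the held-out validation accuracy `Acc_k` of its pretrained base
network (an 80/20 stratified split — training-set accuracy would reward
overfitting). Typicality is measured by order-1 Wasserstein distances: per
channel, all preprocessed samples of a subject are pooled into one empirical
distribution, channelwise distances are computed by the exact sorted-quantile
coupling, and averaged. The trusted score is
`T_k = Acc_k * (1 - Norm(mean_i W(k,i)))` with min-max normalization across
the roster. Edge cases are pinned down deterministically: if all mean
distances are equal the normalization is defined as 0 (so `T_k = Acc_k`);
ties at selection break by higher accuracy, then lower mean distance, then
subject id. Note one consequence of min-max normalization: the subject with
the largest mean distance always scores 0 regardless of accuracy.

The reduction of a multichannel, multi-trial recording to a 1-D
distribution is the one genuinely open design point; pooling per channel
was chosen because it is deterministic, cheap, respects channel
correspondence, and suffices for the structure the simulator plants
(subjects sharing a spatial pattern are measurably closer than scrambled
ones). Trial-resolved or multivariate optimal transport are natural
extensions, not implemented.

### Transfer losses

`coral_loss` is the squared Frobenius distance between unbiased feature
covariances, scaled by `1/(4 d^2)`; `dcca_loss` is minus the sum of the
top-k singular values of `H_ss^{-1/2} H_st H_tt^{-1/2}` with ridge `r` on
both covariances and an eigenvalue floor for the inverse square roots;
`mmd_loss` (ablation arm) is the unbiased multi-bandwidth Gaussian-kernel
estimator. Defaults: `r = 1e-3`, floor `1e-8`, `k = min(d, n-1)` capped at
10. Source and target batches are paired by position with equal sizes and
per-epoch reshuffling, since no trial correspondence exists across
subjects. The class-unconditioned form is implemented exactly as the
equations state it, although the motivating prose speaks of within-class
alignment.

**A scaled-down caveat worth stating plainly.** With flatten dimensions
`d` in the hundreds and batches of 16, the DCCA whitening operates far
below rank: spurious canonical correlations saturate near 1 and the loss
hovers near `-k` regardless of the data, contributing noise rather than
signal to the gradient. In our desk-scale experiments the full
DCCA + CORAL arm therefore trails plain supervised fine-tuning of the
source-initialized model, while still beating the no-transfer baseline
(see the benchmark below). This is an intrinsic small-batch property of
CCA, not an implementation defect — the gradients verify against finite
differences — and it should be remembered when interpreting green transfer
tests.

### Fusion and training

The fusion model concatenates the two source extractors' flattened features
as `[a F_eeg, b F_nirs]` — realizing the accuracy-derived mixing ratio
`a = A_eeg/(A_eeg + A_nirs)`, `b = 1 - a` — and maps them through one fresh
linear layer to two logits; no hidden layers, to limit overfitting on small
target sets. A literal weighted *sum* of the two feature vectors is
dimensionally impossible when `d_eeg != d_fnirs` and contradicts the
direct-connection description, so the weighted concatenation is used. The
total loss `L = L_clf + a L_trans_eeg + b L_trans_fnirs` is optimized with
Adam at learning rate 0.001; the mixing weights are fixed from the target's
pretraining accuracies rather than re-estimated during transfer. Both
extractors remain trainable (a freeze flag exists), target labels come only
from the cross-validation training folds, and all target trials serve
unlabeled transfer batches.

### Evaluation

Stratified 5-fold cross-validation (plain k-fold invites class-skewed folds
at 60 trials); folds are derived once per subject per seed and reused
across all method arms so the Friedman test compares methods on identical
partitions. Metrics use class 0 ("left") as the positive class; per-subject
accuracy averages folds. The Friedman statistic is the tie-corrected rank
chi-square with `df = k - 1`; all-constant rows return statistic 0 and
p = 1 by definition. `stats::friedman.test` and a permutation null serve as
independent cross-checks in the tests, and at five-or-six subjects the
chi-square p is only an approximation to the (discrete) permutation p —
gaps of ~0.1 are expected and are approximation error, not implementation
error.

## The simulator: what it emulates, and what a green test means

`generate_subject()` plants exactly the structure the method assumes:

* paradigm: 2 s cue, 10 s MI, 15 s rest; 15 trials per hand per session,
  two sessions (60 trials), alternating counterbalanced labels;
* EEG: alpha (band-centre, amplitude 1) and beta (20 Hz, amplitude 0.5)
  oscillations weighted by Gaussian sensorimotor bumps per hemisphere, with
  the contralateral amplitude multiplied by `(1 - erd_depth)` during the
  task (0.5 s onset ramp), on a 1/f background whose SD is `snr` times the
  alpha amplitude;
* fNIRS: canonical double-gamma HbO response (unit-peak kernel, mode ~5 s)
  delayed by `hemo_delay`, mirrored HbR at `-0.3 x` (sign is physiology;
  the magnitude is a convention), a 0.1 Hz physiological oscillation, and
  white noise;
* population: profiles drawn i.i.d. (ERD depth ~ truncated N(0.6, 0.15),
  `snr` ~ N(0.5, 0.1) clamped, hemodynamic gain and delay jittered),
  patient-like subjects get the impaired hand's ERD multiplied by 0.2.

Defaults were chosen once for testability at realistic magnitudes — e.g.
`snr = 0.5` keeps the in-band noise floor small enough that the analytic
ERD power ratio `(1 - depth)^2` is recoverable to ±0.05 across the depth
grid — and are not tuned per test. What the simulator does **not** emulate:
volume conduction and channel covariance of real montages, eye/muscle
artifacts, optode coupling drift, serial correlation of hemodynamic noise,
or genuinely nonstationary rhythms. A green pipeline test therefore
establishes internal correctness (the method recovers what was planted,
transfer helps when its premises hold), not clinical performance.

## Numerical choices

* All randomness flows through named integer seeds (`with_seed` restores
  global RNG state); derived seeds stay below 2^31.
* Batch-norm running statistics update only in training mode; evaluation is
  strictly deterministic.
* Adam: beta1 0.9, beta2 0.999, eps 1e-8; early stopping keeps the
  best-validation parameters.
* Wasserstein for unequal sample counts integrates |F_p - F_q| over the
  merged quantile grid (exact, no binning).
* The subject container stores raw little-endian float64, so round trips
  are bit-exact; schema version and truncation are checked explicitly.

## The scaled-down transfer benchmark

`run_transfer_benchmark()` is the package's summary experiment: per seed, a
six-subject population (five default draws plus one deliberately strong
"template" source with deep ERD and low noise — the premise that a good
source exists in the cohort), trusted-score selection with the target
excluded, 20 labeled target trials, and evaluation on the remaining 40.
Over ten seeds at the shipped budgets the full method averaged 86.5%
against 79.3% for the no-transfer baseline — a directional gain consistent
with the motivation for cross-subject transfer, at a scale (8 channels,
32 Hz, tens of epochs) chosen to keep the whole suite within a CPU test
budget. The absolute numbers say nothing about full-scale performance.

## Known limitations

* DCCA's small-batch rank deficiency, discussed above.
* The CNN engine is vectorized but pure R: full-scale inputs (30 x 2000)
  build and forward-propagate fine, but training at that scale is outside
  test budgets.
* Channel-count reduction from dense clinical montages (e.g. 90 fNIRS
  channels to a 36-channel layout) is left to the caller; the data model is
  channel-count-agnostic.
* Single binary task; no online decoding.
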