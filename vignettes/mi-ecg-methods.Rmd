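---
title: "Interpretable beat-level MI detection and localization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable beat-level MI detection and localization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgmi)
```

## The problem

Myocardial infarction (MI) leaves characteristic marks on the surface ECG:
ST-segment elevation or depression, hyperacute or inverted T waves, and —
later — abnormal (deep, wide) Q waves. Which of the 12 leads carry these
marks indicates which ventricular wall is infarcted. `ecgmi` implements a
beat-level pipeline that detects and localizes MI into eight regions
(anterior A, anteroseptal AS, anterolateral AL, inferior I, inferolateral
IL, inferoposterior IP, inferoposterolateral IPL, posterior P) plus healthy
(H) and other-disease (O) classes, while keeping every feature clinically
interpretable.

The pipeline is: wavelet denoising → Mexican-hat QRS detection and fiducial
delineation → seven per-lead *rule features* plus a 1000-sample QT
*ventricular activity* vector → 1000→32 compression (wavelet approximation,
PCA, or locality preserving projection) → a second-order gradient-boosted
tree classifier → stratified 10-fold cross-validation with per-class
sensitivity, specificity, precision and accuracy.

## Denoising

Each lead is decomposed by a multilevel discrete wavelet transform (db6).
The decomposition depth is chosen as `ceiling(log2(fs / 0.7))`, capped at 9
and by the record length, so that the coarsest approximation band lies below
roughly 0.7 Hz; that band — baseline wander — is zeroed. The two finest
detail bands are soft-thresholded with the universal threshold
`sigma * sqrt(2 log n)`, with `sigma` estimated from the median absolute
deviation of the finest band. Intermediate bands, which include the 5–15 Hz
QRS energy that the features depend on, pass through untouched; tests verify
the QRS band is preserved within 10% on clean input.

The transform uses circular (periodized) boundary handling with orthonormal
Daubechies filters. We chose circular over symmetric extension because the
resulting transform is exactly orthogonal — perfect reconstruction and
Parseval hold to machine precision, both of which are asserted in the test
suite — and because it makes the compression stage's coefficient count
exact. One consequence: zeroing the approximation band removes each lead's
own sub-hertz content, including its global mean, so denoised signals are
zero-mean in that band. All downstream features are differences (or ratios
of differences) against a per-beat baseline and are unaffected.

## Delineation

QRS detection computes the continuous wavelet transform with the Mexican-hat
kernel at scales spanning 5–15 Hz, multiplies across scales (energy present
at every scale is reinforced; isolated artefacts are suppressed), and
thresholds the product at 0.4 times a rolling 2-second RMS. Local maxima
separated by a 200 ms refractory period are R peaks; because the threshold
is relative, detection is invariant to amplitude scaling.

Per beat and per lead: Q and S are the nearest local extrema of opposite
polarity to R within 80 ms; the QRS onset (the "I point", the beat's
baseline reference) and the J point (QRS end) are found by a slope rule —
the first sample, moving outward past the flank's slope maximum, where the
absolute slope drops below 10% of the maximal QRS slope. Two refinements
stabilize this textbook rule:

* the threshold is capped at 25% of the flank's own slope maximum, so that
  low-amplitude waves (a small Q) whose flank never reaches 10% of the R
  slope still get an onset at the foot of their flank rather than its crest;
* the scan starts at the *first substantial local* slope maximum along the
  search path, not the global one, so a neighbouring wave (the next beat's
  P) cannot capture the offset; if no sub-threshold sample exists (merging
  waves), the flattest point past the flank is used.

The T wave is searched in `[J + 80 ms, J + 0.6 RR]`; its peak is the
largest absolute deviation from the I-point baseline and its onset/end use
the same slope rule. The P peak (delineated for detection-quality reporting
only; it contributes no features) is the largest baseline deviation in
`[R - 0.30 RR, R - 0.10 RR]`. All window constants are exposed as arguments
and validated against the generator's exact ground truth: on noiseless
synthetic beats, R/Q/S/J land within 20 ms and T onset/peak/end within
40 ms of truth across all ten class archetypes. Delineation is per lead,
with beats matched across leads by the nearest R within 150 ms; per-lead
delineation was chosen (over delineating one reference lead and projecting)
because ST/T morphology genuinely differs by lead.

## Features

For each lead-beat, with `I` the QRS onset used as local baseline:

| feature | formula | unit | meaning |
|---|---|---|---|
| `j_relative` | `J_amp − I_amp` | mV | J-point deviation (ST shift) |
| `st_relative` | `Tstart_amp − J_amp` | mV | ST-segment course |
| `q_ratio` | `(Q_amp − I_amp)/(R_amp − I_amp)` | – | Q depth vs R |
| `q_interval` | `(Q_pos − I_pos)/SR` | s | Q duration |
| `t_ratio` | `(T_amp − I_amp)/(R_amp − I_amp)` | – | T height vs R |
| `tstart_relative` | `T_amp − Tstart_amp` | mV | T upright/inverted |
| `tend_relative` | `T_amp − Tend_amp` | mV | T upright/inverted |

Every formula is a difference or a ratio of differences, so the features are
invariant to constant offsets and the ratios to amplitude scaling — both
asserted exactly in tests. Beats with `R_amp = I_amp` (zero denominator) are
dropped and logged.

The *ventricular activity feature* is the QT segment — QRS onset through
T-wave end, covering ventricular depolarization and repolarization —
resampled to exactly 1000 samples by linear interpolation on a uniform grid
including both endpoints. Linear interpolation was chosen over zero-padding
because the vector is a list of amplitudes over the span, and padding would
distort the wavelet compression that follows. Beats whose QT span reaches
into the next beat's QRS onset are dropped whole (feature purity over
yield), as are beats missing any lead.

## Compression

Each lead's 1000-sample QT vector is reduced to 32 values by one of three
backends:

* **DWT** (default): resample to 1024 points, 5-level db4 decomposition with
  periodized boundaries, keep the level-5 approximation — exactly
  `1024/2^5 = 32` coefficients. The 1000→1024 resample is what makes "db4,
  five levels" and "32 features" simultaneously exact. Approximation-only
  (no detail bands) keeps the smooth summary closest to the waveform.
  Training-free and deterministic.
* **PCA**: training columns centred, top-32 right singular vectors;
  captured variance is checked against a dense eigensolver in tests.
* **LPP**: 7-nearest-neighbour graph with heat-kernel weights
  `exp(-d²/t)`, `t` = mean squared neighbour distance; solve
  `X L Xᵀ a = λ X D Xᵀ a` for the 32 smallest eigenvalues after PCA
  pre-reduction to numerical rank, with a 1e-8 ridge on the denominator.
  `k = 7` and the mean-distance bandwidth are package choices (the usual
  defaults in LPP implementations), exposed as arguments.

Compression is per lead — the fused vector is 12 leads × (7 rule + 32
compressed) = 468 values; rule-only is 84 and ventricular-only is 384. PCA
and LPP are fitted inside each cross-validation training fold only (fold
hygiene is asserted by a test); the DWT backend has nothing to fit.

## Classifier

The classifier is a second-order gradient-boosted tree ensemble trained on
the softmax cross-entropy loss. Each round computes per-sample gradients
`g = p − 1{class}` and diagonal Hessians `h = p(1−p)` at the current scores
and fits one regression tree per class by exact greedy split search. A
split's gain is

```
1/2 [ G_L²/(H_L+λ) + G_R²/(H_R+λ) − G²/(H+λ) ] − γ
```

accepted only when positive, with ties broken to the lowest feature index
and then the lowest threshold; leaf weights are `−G/(H+λ)` times the
learning rate. The split kernel is in C++ (this inner loop is why every
boosted-tree library compiles it); its results are property-tested against
exhaustive enumeration on all small tables, and whole-model predictions are
cross-checked against an independent boosted-tree library on toy data.

Defaults: depth 6, learning rate 0.1, `λ = 1`, `γ = 0`, column subsample
0.8 per tree, up to 200 rounds with optional early stopping on training
log-loss (the cross-validation wrapper uses 60 rounds with early stop at
1e-3, which on the synthetic task converges long before the cap). Multiclass
is handled as one tree per class per round on shared softmax scores; the
boosting equations themselves are single-output and silent on multiclass, so
this standard construction is a package choice.

## Evaluation

`confusion_counts()` builds the pooled confusion matrix over held-out
predictions in a fixed clinical class order; `class_metrics()` collapses it
one-vs-rest and reports `Se = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
`+p = TP/(TP+FP)`, `Acc = (TP+TN)/total` in percent at full precision,
rounding only for display; zero-denominator metrics are `NA`, never 0.
`kfold_cv()` uses stratified beat-level folds (deterministic given a seed),
fits compression and classifier inside training folds, and reports both the
pooled matrix (primary) and per-fold accuracies with their mean. Beat-level
folds match the protocol the pipeline targets; note that on real data with
several beats per patient, beat-level cross-validation is optimistic
compared to patient-grouped splits — group by record when that matters.

## The synthetic generator

`simulate_ecg()` renders beats as five Gaussian bumps (P, Q, R, S, T) plus a
raised-cosine-edged ST plateau running from just after the S wave to the T
onset, concatenates them with jittered RR intervals, applies per-lead gains,
and adds sinusoidal baseline wander and white noise. Because the bump
parameters are known, every beat carries exact fiducial indices and the true
ST offset — this is what makes delineation and feature recovery testable,
and is why a parametric model was chosen over resampling real recordings.

Class archetypes follow the textbook signatures — ST elevation with
hyperacute T (A), ST elevation with inverted T (AS), abnormal Q with ST
elevation (AL), abnormal Q with inverted T (I, IL, IPL), reciprocal ST
depression with tall T (IP, P), low flat T with reduced R (O) — each
confined to a clinically motivated lead subset (e.g. II/III/aVF for inferior
classes, V1–V4 for anteroseptal). The archetype magnitudes (e.g. 0.2 mV ST
elevation, Q at 30–38% of R) are package constants chosen to be
physiologically plausible; no published per-class morphology parameters
exist for them. Two deliberate simplifications: wave *timing* is shared
across leads within a beat (so truth fiducials are a per-beat property), and
archetypes keep a margin between the ST offset and the T amplitude so that
the T peak remains the largest baseline deviation in its window. Defaults:
1000 Hz sampling (360 Hz also supported), 0.8 s mean RR with 0.02 s jitter,
0.1 mV/0.3 Hz wander, 0.02 mV noise, 5% morphology jitter.

What passing tests on this generator do **not** show: robustness to
electrode motion, arrhythmia, biphasic T waves, P-wave variability, or
patient-level generalization on real recordings. The generator is a
correctness harness, not a claim of clinical fidelity.

## Numerical choices and degenerate inputs

* Wavelet filters are the standard db4/db6 orthonormal coefficients; odd
  lengths are padded by repeating the last sample, with original lengths
  restored on inversion.
* The CWT convolution is FFT-based at a 2-3-5-smooth padded length
  (arbitrary record lengths would otherwise hit quadratic mixed-radix
  FFTs).
* Split-gain ties in the tree builder are resolved with a 1e-12 relative
  slack so float noise cannot override the lowest-feature/lowest-threshold
  rule.
* All sample indices are 1-based in memory (R convention) and written
  0-based to annotation/truth files, stated in each file.
* Problem sizes in the test suite: delineation and recovery run on 60–200
  noiseless beats; the end-to-end cross-validation property runs on 2000
  beats (200 per class) with 0.02 mV noise, 10-fold, for each of the three
  feature sets.

## Known limitations

* The WFDB reader supports format 16 only (the common case for 12-lead
  resting records); other formats are rejected with a clear error.
* The delineator assumes a dominant upright or inverted R and a single T
  bump; biphasic T subtyping is out of scope.
* LPP's out-of-sample mapping is the learned linear projection; points far
  from the training manifold are extrapolated linearly.
* Missing values are not supported in the classifier; the feature stage
  never emits them (beats are dropped whole instead).
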