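---
title: "Heartbeat detection from bed-frame acceleration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heartbeat detection from bed-frame acceleration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedbeat)
```

## The problem

Ballistocardiography (BCG) senses the tiny recoil of the body — here, of a
bed frame — caused by cardiac ejection of blood. A 3-axis accelerometer
bolted to the bed, sampled at 250 Sa/s, sees a short transient at every
heartbeat, strongest along the head–foot (X) axis. A finger
photoplethysmograph (PPG) recorded simultaneously provides ground truth:
each peak of the pulse waveform marks one beat.

`bedbeat` turns this into a supervised classification problem. Signals are
cut into non-overlapping windows of 125 samples (0.5 s); each window gets
12 features and one binary label — did a PPG-detected beat fall inside this
window? Eight classifiers are then compared under stratified 10-fold
cross-validation, and the best one is examined per participant with
leave-one-subject-out evaluation.

A full study comprises 10 participants × 4 lying positions (prone, back,
right side, left side) × 180 s, so each recording has
45,000 samples per channel and the pooled design matrix has

$$N_\mathrm{window} = \frac{250 \times 180 \times 4 \times 10}{125} = 14{,}400$$

rows. No public dataset accompanies this problem, so the package includes a
first-class simulator that reproduces this structure with known ground
truth; every claim the test suite makes is made against simulated data.

## The signal model behind the simulator

Each recording is generated as follows.

* **Rhythm.** Inter-beat intervals are `60/heart_rate_bpm` seconds, each
  multiplied by `1 + U(-j, j)` with jitter fraction `j` (default 0.1) and
  floored at 0.3 s (a refractory bound). The first beat starts at a uniform
  phase offset so recordings do not all begin on a beat. Beats are kept
  only if their pulse peak — `ppg_delay_s` later — still falls inside the
  acquisition; the pulse reference cannot mark a beat whose pulse wave
  arrives after the recording stops. The resting heart-rate band is
  40–120 bpm (0.6–2 Hz); the simulator warns outside it, and
  `simulate_dataset()` draws per-participant rates from 50–90 bpm.
* **Beat transient.** Each beat injects an exponentially damped sinusoid:
  amplitude 1, decay constant 0.15 s, oscillation 8 Hz. The shape is the
  simplest waveform with realistic bandwidth inside the analysis band; no
  claim of physiological J-wave morphology is made. The transient couples
  into the axes via `axis_mix` (default `c(1, 0.35, 0.25)`, X-dominant),
  permuted and attenuated per lying position (side positions swap the
  lateral axes; non-prone positions attenuate). This gives per-position
  variation without pretending to be a physiological position model.
* **Respiration and noise.** A sinusoid at 15 breaths/min (0.25 Hz),
  amplitude 0.4, enters with a Z-dominant axis profile; it lies below the
  0.5 Hz filter edge, so it exercises the high-pass side of the filter.
  White Gaussian noise (sd 0.1) is added per axis. Acceleration units are
  arbitrary but consistent — every downstream feature is scale-covariant,
  so only ratios such as beat amplitude : noise sd (10:1 by default)
  matter.
* **Pulse channel.** A unit Gaussian bump (sd 0.05 s) centred
  `ppg_delay_s = 0.2` s after each beat, plus noise (sd 0.02). Only peak
  timing matters downstream, so the bump shape is not modelled further.
* **Determinism.** One integer seed per recording drives all draws;
  identical configs give bit-identical recordings. Dataset-level seeds
  derive per-recording seeds reproducibly.

What the simulator does **not** emulate: movement artefacts, posture
changes mid-recording, arrhythmias, inter-beat amplitude variation, sensor
drift, and the heavy-tailed noise of real hardware. Passing tests on this
generator demonstrates that the pipeline's plumbing, arithmetic and
learning machinery are correct and that the classifiers can recover a
clean BCG signal — not that the printed accuracies would be reproduced on
human data, which are not publicly deposited.

## Preprocessing

All four channels pass through a Butterworth bandpass at 0.5–20 Hz
(overall order 4), applied forward–backward. Zero-phase filtering is a
deliberate choice: a causal filter would delay the acceleration channels
relative to the PPG-derived labels and bias every window label near a
window boundary. The implementation uses reflected-edge padding with
step-matched initial conditions, so a constant input is annihilated to
numerical precision and edge transients are negligible. The analytic
magnitude response is exposed (`bandpass_response()`): DC is fully
rejected, 5 Hz passes with gain ≈ 1, 50 Hz mains is attenuated below 0.05
(gains quoted for the doubled, forward–backward application).

`delta_abs()` is the rectified first difference
`|x[i+1] − x[i]|` — a crude high-pass emphasizing the beat transient. It
is computed **within** each 125-sample window (124 values), never across
window boundaries, so no feature leaks neighbouring samples.

Because the bandpassed channels are zero-mean, plain window sums would be
uninformative; by default (`rectify_acc = TRUE`) the sum/std/max features
are taken on `|signal|`, so they carry energy information. The flag exists
because the plain-signed reading is also defensible; both are supported
and only the default is asserted on.

## Features and labels

Each window yields 12 features in a frozen column order:
`Xsum, Xstd, Xmax, dXsum, dXstd, dXmax, Ysum, Ystd, Ymax, Zsum, Zstd,
Zmax` — sums, standard deviations and maxima per axis, plus the same
statistics of the X first-difference magnitude. Standard deviations use
the population convention (divide by *n*); this is a declared package
convention, fixed so the loop-based oracle tests are exact.

Labels come from the filtered pulse channel: local maxima with topographic
prominence at least 0.3 × the channel's amplitude range, thinned to a
minimum separation of 0.3 s (higher peaks win). Window `w` is labelled 1
iff at least one peak index falls in its half-open sample span. At 250 Sa/s
and 125-sample windows the expected positive fraction is
`heart_rate_bpm/60 × 0.5`, about one half at 60 bpm, so the classes are
roughly balanced by design.

## The model roster

Eight classifiers run through one `fit_model()`/`predict()` contract, so
the comparison harness never special-cases:

| Spec | Implementation | Pinned configuration |
|------|----------------|----------------------|
| LR   | `stats::glm`, binomial | threshold 0.5 |
| LDA  | `MASS::lda` | defaults |
| KNN  | `class::knn` | k = 5 (majority vote) |
| CART | `rpart` | Gini splits, library stopping rules |
| NB   | `e1071::naiveBayes` | Gaussian class-conditionals |
| SVM  | `e1071::svm` | RBF kernel, cost 1 |
| RF   | `randomForest` | 100 trees |
| DL   | own Rcpp MLP | 12→9→9→1, ReLU/sigmoid, SGD, lr 0.1, 100 epochs, batch 10 |

The MLP is written in the package (RcppArmadillo) because no installed
library provides the exact architecture: two ReLU hidden layers of nine
neurons, one sigmoid output, plain mini-batch SGD. The loss is binary
cross-entropy (the natural partner of a sigmoid output for binary
classification); weights use He initialization for ReLU layers and Glorot
for the output — both package decisions, as is k = 5 for KNN and the RBF
kernel for the SVM, none of which the study pins down. All randomness in
training flows from R's RNG under the spec's seed, so two fits with the
same data, spec and seed are identical, MLP included.

Inputs are z-scored for the scale-sensitive learners (LR, KNN, SVM, DL),
with centre and scale estimated on the training rows only — inside each
cross-validation fold — to avoid leakage. Trees, naive Bayes and LDA see
raw features. Probability models threshold at 0.5.

## Evaluation

`confusion()` counts TP/FP/TN/FN; `metrics_from_confusion()` derives
per-class precision and recall, per-class F1 (harmonic mean), the macro
average (unweighted mean of the two F1s), the support-weighted average,
and accuracy. Zero denominators yield 0 and set a `degenerate` flag; the
study's data never hit this case, but degenerate folds must not crash.

`kfold_compare()` builds one stratified fold assignment (classes shuffled
separately under the seed, dealt round-robin with a rotating offset so
fold sizes are exactly equal whenever the total divides by k — 14,400/10
gives ten folds of 1,440) and reuses it byte-identically for every model.
It reports mean and standard deviation of the fold accuracies (std across
the folds of the single run) and the mean wall-clock time to train and
test one fold. Timing is informational: it depends on the host, is
excluded from the JSON manifest, and can be excluded from the CSV
(`include_timing = FALSE`) when byte-identical reports are required —
that is the one field that legitimately differs between identical runs.

`per_person_eval()` interprets the per-person protocol as
leave-one-subject-out: for each participant, train on the other
participants' windows and test on that person's 1,440 windows (4 positions
× 360). This interpretation is recorded in the result's `protocol`
attribute; a pooled-split reading is also conceivable, but
leave-one-subject-out is the stricter and more standard choice for
subject-wise generalization. Reports round to 2 decimals (per-person
table) and 3 decimals (comparison table); unrounded values are retained in
the returned objects and the JSON manifest.

## Numerical and degenerate-input choices

* Filter: even overall order required; cutoffs must be below Nyquist;
  channels must exceed the padding length (3 × the coefficient count).
* Peak detection: a flat channel returns no peaks with a warning; ties in
  the refractory thinning resolve to the earlier peak.
* Windowing: trailing partial windows are discarded everywhere
  (`floor(n/125)`), matching the exact division of the study design.
* Single-class training data is rejected with the missing class named;
  constant features under standardization fall back to centring only.
* `sim_config` validates jitter < 0.5 so intervals stay positive.

## Problem sizes used by the test suite

Unit tests run on a 2-participant × 2-position × 20 s dataset (160
windows). The end-to-end comparison test and the acceptance script use the
full study geometry — 10 × 4 × 180 s, 14,400 windows — with the default
noise settings, where the random forest's cross-validated accuracy
comfortably exceeds both 0.85 and the majority-class baseline by 0.15.
These margins are sanity floors for signal recovery on clean synthetic
data, not reproductions of any published accuracy.

## Known limitations

* The simulator's SNR is a free parameter; no published amplitude figures
  exist to calibrate it, so defaults are documented choices.
* Leave-one-subject-out and the k-fold std definition are interpretations
  where the protocol is ambiguous; both are pinned and surfaced in output.
* The pipeline classifies window-level beat presence only — no beat-to-beat
  intervals, HRV, or arrhythmia analysis.
* Timing columns measure this host and mean nothing elsewhere.
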