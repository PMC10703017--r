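---
title: "EEG-based Parkinson's disease classification: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-based Parkinson's disease classification: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pdeeg)
```

## The problem and the pipeline

Resting-state EEG carries spectral signatures that differ between people
with Parkinson's disease (PD) and healthy controls, but the signals are
noisy, non-stationary and contaminated by artifacts. `pdeeg` implements a
complete classification pipeline — preprocessing, Gaussian-window
time-frequency features, recurrent neural classification, subject-level
cross-validation — together with a synthetic cohort generator, so every
claim the package makes can be verified end to end on data with known
ground truth.

## The synthetic cohort generator

Each recording is a channels × samples matrix in microvolts built as

* per-band oscillations: white Gaussian noise band-passed into the
  canonical bands (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma
  30–100 Hz), each scaled to `sqrt(relative power) × amplitude` (default
  amplitude 10 µV). Filtered noise, not sinusoids: pure tones would make
  the classification task trivially easy and spectrally unlike EEG.
* broadband sensor noise (`noise_sd`, default 2 µV), a mains sinusoid
  (50/60 Hz, default 1 µV, random phase per channel), and blink-like
  transients: one-sided exponential pulses of ≈0.3 s, amplitude 5–10× the
  background SD, on the first quarter of channels ("frontal"), with a
  refractory gap of two pulse widths so transients never overlap. The
  ground-truth interval records the portion of the pulse above 10% of its
  peak — beyond that the transient is indistinguishable from background.
* a per-subject, **per-channel** multiplicative gain drawn uniformly from
  `[1 − gain_sd, 1 + gain_sd]` (default 0.1). Electrode contact and
  impedance vary by site, so a subject's amplitude signature is
  multichannel. This design choice matters for the leakage experiment
  below: a single scalar gain gives subjects a one-dimensional signature
  whose values collide across subjects, whereas per-channel gains make
  subjects reliably identifiable from single segments — which is exactly
  the mechanism that inflates segment-level cross-validation.

The class contrast defaults to elevated beta-band power in the PD-like
class (`beta_ratio`). This is a *stand-in*: the underlying clinical
literature does not settle what distinguishes PD resting EEG, and nothing
here should be read as a claim about PD electrophysiology. What the
generator provides is a controllable effect size with exact ground truth.

What it does **not** emulate: volume conduction and channel covariance,
1/f spectral slopes, non-stationarity within a recording, medication
state, or realistic artifact diversity (only blinks and broadband noise).
A pipeline that passes these tests is verified as *software operating on
band-structured signals*; performance on clinical recordings is a separate
empirical question.

## Preprocessing

* Band-pass: Butterworth of configurable order (default 4) between 0.5 and
  100 Hz, applied forward–backward (zero phase). The filter is realized as
  cascaded second-order sections with zeros paired to their nearest poles:
  a direct-form order-8 band-pass whose lower edge sits at 0.001 of
  Nyquist is numerically ill-conditioned (linearity errors around 1e−6),
  while the section cascade is exact to ≈1e−11.
* Notch: a single constrained biquad (Q = 30 by default) at 50 or 60 Hz.
* Segmentation: non-overlapping 1024-sample windows by default (2 s at
  512 Hz, ~90 segments from a 3-minute recording); window and hop are
  sample counts, intervals half-open `[start, end)`, 0-based.
* Artifact rejection: a segment is dropped when its peak absolute
  amplitude exceeds `amp_threshold`. Optionally, each segment is first
  decomposed by ICA (a compact symmetric FastICA with logcosh contrast,
  written in-package and seeded deterministically) and components whose
  time courses have kurtosis above 5 are zeroed — blink and spike sources
  are strongly super-Gaussian, ordinary EEG is not. These thresholds are
  surrogates chosen against generator ground truth; clinical data cleaned
  by visual inspection follows no single rule.
* Normalization: per-channel z-scoring either per segment or from
  training-set statistics that are then *reused* on held-out data
  (`train_only`), the variant all cross-validation code uses, because
  estimating statistics on test data is a leakage channel.

## The Gabor transform

The analysis value at time $t$ and frequency $f$ is the inner product of
the signal with a translated, modulated Gaussian atom:

$$X(t,f) = \frac{1}{f_s}\sum_\tau x(\tau)\,
  e^{-(t-\tau)^2/2\sigma_t^2}\, e^{-i2\pi f(\tau-t)}.$$

The atom itself is $g(t,f) = e^{-t^2/2\sigma_t^2} e^{i 2\pi f t}$. The
transform is phase-referenced at the window center, which leaves all
magnitudes identical to the textbook convention and makes a tone at $f_0$
peak at the $f_0$ bin — the property the test suite asserts analytically.
Numerical choices: the kernel is truncated at `truncation × sigma_t`
(default 6, where the Gaussian is below 2e−8), edges are zero-padded, the
sum is scaled by $1/f_s$ as a Riemann approximation of the integral, and
analysis times sit on a hop grid. The dense untruncated sum is kept as a
test oracle; the truncated implementation matches it to 1e−6 relative.
Features for the classifier are per-channel log-magnitudes
(`log(m + 1e-8)`; magnitudes span decades) concatenated across channels,
giving a `T × (channels · frequencies)` sequence per segment.

Defaults: `sigma_t` 0.1 s (a ~1.6 Hz frequency-domain SD: band-level
resolution at EEG rates), 1–45 Hz in 1 Hz steps at 512 Hz full scale. The
published architectures declare a 178-step input; integer hops cannot land
exactly on 178 for a 1024-sample window, so sequence length is governed by
`hop` and the presets keep 178 for parameter accounting.

## The classifiers

The LSTM cell, bidirectional composition and densely linked stacking are
implemented from their defining equations (see `?lstm_cell_step`,
`?bilstm_forward`, `?dense_link_forward`), with a literal independently
written transcription of the same equations serving as the test oracle at
1e−12. Points where the published description required interpretation:

* Dense linking uses **concatenation** (layer $l$ consumes
  $[d^0,\dots,d^{l-1}]$ and emits $d^l = [h^l, x_t]$), not additive
  residuals; the skip list includes *all* preceding layers.
* A non-sequence bidirectional output is $[h_f(T), h_b(1)]$ — the final
  step of each direction — the only convention consistent with the printed
  output widths.
* Cross-entropy is the standard categorical form
  $\mathrm{logsumexp}(\varphi) - \varphi_{\text{true}}$, stabilized by max
  subtraction.
* Multi-scale fusion averages window means over all windows of each width,
  then averages across widths, so constant score sequences are fixed
  points; the literal printed divisor $1/((T-p)p)$ is available behind
  `literal = TRUE` for comparison.
* Batch-norm parameter accounting is 4 per feature (scale, shift, two
  running moments) — the convention that matches the printed counts;
  training updates only scale and shift. Two printed counts (the
  first-layer LSTM and final dense of the plain-LSTM table) contradict
  their own printed shapes and are excluded from accounting checks.

Training is full backpropagation through time in R: Adam (lr 0.001, batch
64, up to 20 epochs, dropout 0.4 — the published tuned values), forget-gate
bias initialized to 1, Glorot-uniform weights, early stopping on
validation loss with patience 5 and best-epoch restoration. Analytic
gradients are verified against central finite differences through every
layer type. Sequence-output heads attach the segment's label to every time
step; subject-level decisions fuse all of a subject's per-step
positive-class probabilities with the multi-scale window fusion
(widths 1, 3, 5) and threshold at 0.5.

## Evaluation protocol

The 80-10-10 split and the six-fold cross-validation are independent
evaluation modes (the source material reports both without composing
them). Cross-validation defaults to **subject-level** folds: no individual
contributes segments to both a training and a test fold. Segment-level
folds are available behind `level = "segment"` precisely to demonstrate
why they should not be used: on a cohort with *zero* class effect but
per-channel subject gains (gain_sd 0.5, "strong" variability), the
segment-level protocol recovers subject identity rather than class and
scores 0.25–0.4 above the subject-level protocol's chance-level accuracy.
Within each fold an inner stratified validation slice (~1/6 of training
subjects, at least one per class) drives early stopping, and feature
standardization uses training-fold statistics only.

## Problem sizes used by the shipped experiments

The experiment code (acceptance script, demo config) runs cohorts of
15 PD + 16 HC subjects at 4 channels, 128 Hz, 30 s per subject, gamma
capped at 55 Hz below Nyquist, 2-s segments, 20 analysis frequencies
(2–40 Hz), 16 time steps per segment, and the all-sequence bidirectional
preset scaled to 8 units per direction — sizes chosen so a complete
six-fold experiment runs in well under a minute on one CPU while keeping
every structural property of the full-scale task (multichannel spectra,
~15 segments per subject, stratified folds of 2–3 subjects per class).
The leakage contrast uses 10 + 10 subjects at 60 s with 50 epochs, where
the longer recordings give the segment-level protocol enough per-subject
segments to memorize. With a beta-power ratio of 3 the classification
problem is deliberately easy (the spectral effect is far larger than any
plausible clinical one); the experiment validates the pipeline's
correctness and leakage hygiene, not clinical attainability.

## Known limitations

* The recurrent stack is pure R; it is fast at the shipped scales but not
  engineered for full-scale (32-channel, 512 Hz, 178-step) training runs.
* ICA unmixing on short segments is approximate; the kurtosis rule targets
  blink-like sources only.
* EDF/BDF round trips are limited by the formats' 8-character ASCII
  physical-range fields (~6 significant digits) on top of 16/24-bit
  quantization.
* AUC is computed by average ranks (ties counted half); curve points are
  emitted at distinct thresholds only.
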