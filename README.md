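# pdeeg

Automated identification of Parkinson's disease (PD) from resting-state
multichannel EEG, built as a fully reproducible R pipeline:

1. **Synthetic EEG cohorts** — band-structured oscillatory recordings
   (delta/theta/alpha/beta/gamma as filtered Gaussian noise), 50/60 Hz mains
   interference, frontal blink transients with ground-truth intervals, and a
   controllable class contrast (by default, elevated beta-band power in
   PD-like subjects). Every downstream stage is testable with no external
   data.
2. **Preprocessing** — zero-phase Butterworth band-pass (0.5–100 Hz) applied
   as cascaded second-order sections, IIR notch at 50/60 Hz, fixed-window
   segmentation, artifact rejection by peak amplitude with optional
   ICA-assisted removal of high-kurtosis (blink/muscle) components, and
   leakage-safe normalization.
3. **Gabor time-frequency features** — the Gaussian-window transform

   X(t, f) = (1/fs) Σ_τ x(τ) · exp(−(t−τ)²/(2σ_t²)) · e^(−i2πf(τ−t)),

   evaluated on a hop grid of analysis times and a frequency grid, with
   log-magnitude channel-stacked spectrograms as classifier input.
4. **Recurrent classifiers from first principles** — the gated LSTM cell
   (i, f, o = σ(W·[h_{t−1}, x_t] + b); c_t = f⊙c_{t−1} + i⊙tanh(W_c·[h,x]+b_c);
   h_t = o⊙tanh c_t), bidirectional composition [h_f(t), h_b(t)], densely
   linked stacking in which layer *l* consumes the concatenation
   [d⁰, …, d^{l−1}] and emits d^l = [h^l, x_t], multi-scale sliding-window
   score fusion, categorical cross-entropy, and full backpropagation through
   time with Adam — no deep-learning framework required.
5. **Evaluation** — stratified 80-10-10 splits, stratified six-fold
   cross-validation at the *subject* level (no individual contributes
   segments to both train and test folds), confusion-matrix metrics
   (accuracy, precision, recall/sensitivity, specificity, F1), and
   rank-formulation ROC/AUC.

Declarative model specs reproduce the published layer architectures
(`model_preset("table1_lstm" | "table2_dlblstm" | "table3_bilstm")`) with
exact per-layer parameter accounting, e.g. a 128-unit-per-direction
bidirectional block over 32 features counts 2·4·(128·(32+128)+128) = 164,864
parameters.

## Worked example

```r
library(pdeeg)

res <- run_pipeline(list(
  seed = 11,
  simulate = list(n_pd = 15, n_hc = 16, beta_ratio = 3),
  evaluate = list(k = 6, level = "subject")
))
print(res$metrics)
```

Output (4-channel, 128 Hz, 30 s synthetic cohort; ~20 s on one CPU):

```
features: 405 segments x 16 steps x 80 features
fold 1/6: accuracy 1.000 (n = 6)
...
fold 6/6: accuracy 1.000 (n = 5)
       metric mean sd
1    accuracy    1  0
2   precision    1  0
3      recall    1  0
4 specificity    1  0
5          f1    1  0
6         auc    1  0
```

A beta-power ratio of 3 is an easy, well-separated contrast: six-fold
subject-level CV classifies all 31 synthetic subjects correctly. With
permuted labels the same pipeline falls to chance (≈ 0.5) — the null
control that shows the accuracy comes from the class contrast, not from
leakage. Model summaries are available via
`describe_model("table2_dlblstm")`, and the same pipeline runs from a shell
through `inst/cli/pdeeg.R` (subcommands `simulate`, `run`, `describe`,
`demo`).

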