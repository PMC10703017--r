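Package: pdeeg
Title: Parkinson's Disease Detection from EEG with Gabor Spectrograms and
    Densely Linked Bidirectional LSTMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for automated identification of
    Parkinson's disease from resting-state multichannel EEG.  Recordings are
    filtered (band-pass, notch), segmented, cleaned of blink and spike
    artifacts, converted to time-frequency feature sequences with a
    Gaussian-windowed (Gabor) transform, and classified with recurrent
    networks built from first principles: LSTM cells, bidirectional
    composition, densely linked stacking with concatenation skip
    connections, multi-scale sliding-window score fusion, and exact
    per-layer parameter accounting.  Includes a synthetic EEG cohort
    generator with band-structured oscillations, line noise and blink
    transients, stratified subject-level cross-validation, and a full
    classification metric suite (confusion matrix, sensitivity,
    specificity, F1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
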