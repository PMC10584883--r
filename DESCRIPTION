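Package: cardiosleep
Title: Sleep Stage Classification from Cardiorespiratory and Body Movement
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify five-class sleep stages (WK, REM, N1, N2, N3)
    per 30-second epoch from four physiological parameters derived from
    cardiorespiratory and leg-EMG recordings: heart rate from beat-to-beat
    R-R intervals, respiratory rate from a complex-Morlet wavelet spectrum,
    the phase coherence between respiratory sinus arrhythmia and respiration
    (Hilbert analytic-signal phases), and body movement frequency from
    thresholded EMG bursts. A bidirectional LSTM sequence classifier, written
    in vectorized base R, is trained with Adam, gradient clipping, a stepped
    learning-rate schedule and early stopping, and evaluated epoch-by-epoch
    with balanced accuracy, a pooled-Youden kappa and an F1-type score,
    together with derived sleep parameters (TST, SL, WASO, REM%, NREM%, SE)
    compared by Deming regression and Bland-Altman analysis. A stage-labelled
    synthetic overnight-recording generator makes the full pipeline testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
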