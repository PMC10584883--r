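---
title: "Methods: sleep staging from cardiorespiratory and movement signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep staging from cardiorespiratory and movement signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Clinical sleep staging assigns one of five labels (WK, REM, N1, N2, N3) to
every 30-second epoch of an overnight polysomnogram, normally from EEG/EOG.
This package implements an EEG-free alternative: four physiological
parameters are extracted per epoch from cardiorespiratory and leg-EMG
channels and a bidirectional LSTM sequence model maps the whole night's
parameter sequence to a stage sequence.

The four parameters are:

* **HR** — heart rate, from the beat-to-beat R-R interval (RRI) tachogram,
  spline-resampled to a uniform 10 Hz grid; `HR = 60000 / RRI(ms)`.
* **RR** — respiratory rate, `60 f_R`, where the dominant respiratory
  frequency `f_R` maximizes the time-averaged complex-Morlet wavelet power
  of the 0.05–0.6 Hz band-passed respiration signal in a 20 s window.
* **λ** — cardiorespiratory phase coherence,
  `λ(t_k) = |(1/N) Σ_j e^{iψ_j}|²` over the trailing `N = 100` samples
  (10 s at 10 Hz), where `ψ` is the instantaneous phase difference between
  respiratory sinus arrhythmia (RSA; the RRI series band-passed to ±50% of
  `f_R`) and respiration, both phases obtained from the Hilbert analytic
  signal. `λ = 1` means perfect phase locking; independent phases give
  `E[λ] = 1/N`.
* **BMF** — body movement frequency: the EMG is band-passed 1–30 Hz and
  normalized by a robust baseline SD; a 10 s window scores a movement when
  any sample exceeds 3 baseline SDs, and the epoch's BMF is the count of
  movement windows divided by 30 s.

All parameters are computed on 10 s windows sliding by 5 s, smoothed with a
30 s (6-point) median filter, and aggregated per epoch as the mean of the
six window values (BMF uses the count rule above). A sixth label, LV
("getting out of bed"), marks spans where all channels drop out; LV epochs
produce all-zero features, and four LV epochs are padded onto each end of
every night so the model sees the minority LV state at every sequence
boundary. Before any agreement metric, LV is merged back into WK and the
stages are encoded deepest-first (N3=1 … WK=5).

## The classifier and its training protocol

The network is `input(4) → [biLSTM(128 per direction) → dropout(0.2)] × 3 →
dense(6) → softmax`, trained with Adam on the masked categorical
cross-entropy over all six classes. The full-scale defaults
(`stager_config()`): initial learning rate 1e-2 reduced to one-hundredth
every 50 epochs, L2 regularization 0.1, global L2-norm gradient clipping at
2, at most 5000 epochs, early stopping with patience 50 on the validation
loss (improvement threshold 1e-5), and a single "longest-sequence"
mini-batch holding all training nights sorted by length and zero-padded at
the end. Padded positions are masked out of the loss and all metrics.
Because no deep-learning backend is assumed, the network — forward pass,
backpropagation through time, Adam, clipping, schedule, dropout — is
implemented in vectorized base R; training histories expose the realized
learning rate and post-clip gradient norm so the protocol is auditable.

Evaluation follows leave-one-subject-out cross-validation in which the
held-out night also serves as the early-stopping validation set. This is
the stated protocol of the staging literature this package follows, but it
lets the stopping criterion see the evaluation subject and is therefore
prone to optimistic bias; treat per-subject metrics accordingly.

Design choices where the protocol was open:

* The loss runs over all six classes including LV, since LV labels are
  deliberately added to the training data; a five-class variant would
  silently ignore a trained output.
* Features are z-scored with training-fold statistics; all-zero LV rows are
  transformed like any other input (they map to the standardized image of
  zero), keeping the transform affine and invertible.
* Weight initialization is uniform within ±1/√fan-in with forget-gate
  biases at 1; argmax ties break toward the lower class index in the fixed
  order N1, N2, N3, REM, WK, LV.
* `fast_stager_config()` is the desk-scale profile used by the package's
  own experiments and tests: 1 biLSTM layer, 32 units, 200 max epochs, and
  L2 = 1e-4. The full-scale L2 of 0.1 is calibrated to a 3×128 network
  trained for thousands of epochs; on a 32-unit network trained a few
  hundred epochs it would dominate the Adam updates, so the small-network
  default is used there.

## Agreement metrics

Overall performance uses three formulas computed from class-pooled
one-vs-rest tallies: with pooled sensitivity `S = ΣTP_c/(ΣTP_c + ΣFN_c)`
and pooled specificity `P = ΣTN_c/(ΣFP_c + ΣTN_c)`,

* balanced accuracy `= (S + P)/2`,
* κ `= S + P − 1`,
* F1 `= 2S/(2 + S − P)`.

These are implemented verbatim. Note that this κ is Youden's J computed on
pooled tallies, not the conventional chance-corrected Cohen's κ; the
conventional statistic is available separately as `kappa_cohen()` and the
two are never substituted for each other. The same three formulas applied
to a single class's tallies give the per-class metrics. Undefined
components (a class absent from the truth) propagate as NaN with a warning
rather than silent zeros.

Six sleep parameters are derived per hypnogram — TIB, TST, SL, WASO
(= TIB − SL − TST by construction), REM%, NREM% (of sleep epochs) and
SE = 100·TST/TIB — and predicted-vs-reference parameters are compared with
Deming regression (error-variance ratio 1, i.e. orthogonal regression, by
default), Bland–Altman bias and 1.96-SD limits of agreement, and a Spearman
test of difference against average for proportional bias. "Bedtime" is the
first epoch of the (padding-stripped) record and sleep onset the first
epoch scored as any sleep stage; percentages are computed on epoch counts,
which is equivalent to minutes at the fixed 30 s epoch length.

## What the synthetic generator emulates

No clinical recordings ship with the package, so a generator produces
stage-labelled nights with the qualitative stage-conditional structure the
analysis relies on:

* a first-order Markov hypnogram at 30 s resolution
  (`default_transition_matrix()` favours realistic persistence and stage
  ordering; its stationary stage mix is configuration, not a claim);
* respiration as a narrowband oscillation whose instantaneous frequency
  drifts around the stage's `resp_freq` (Ornstein–Uhlenbeck drift, 30 s
  correlation time, clipped to the 0.05–0.6 Hz analysis band so the wavelet
  peak stays defined);
* beats by integrating an instantaneous RRI
  `60000/(mean_hr + wander) + rsa_amplitude · sin(resp_phase + θ)`, where
  the wander is AR(1) with coefficient 0.999 at beat resolution (the
  simplest process giving slow, stage-plausible drift) and θ is an OU
  process with 5 s correlation time whose stationary SD `phase_jitter_sd`
  is the ground-truth dial for λ: 0 yields λ ≈ 1, large values push λ
  toward the 1/N noise floor;
* EMG as a bounded narrowband baseline tone plus Poisson-placed 0.5 s
  bursts of `movement_amp` baseline-SDs. The baseline is deliberately
  light-tailed (a tone never exceeds ~1.4 robust SDs) so that the
  single-sample 3-SD threshold rule has a near-zero false-alarm rate, as it
  must have had on the tonic EMG of real recordings for the published rule
  to be usable; heavy-tailed Gaussian baselines would trigger almost every
  window and are not what this detector is meant for.
* LV epochs zero every channel and carry no beats, so "missing signals
  provide no information".

The default profiles encode the qualitative ordering: λ highest and stable
in N3/N2, lower in N1, low and fluctuating in REM; HR wander largest in
REM; movements most frequent in WK. `separated_stage_profiles()` and
`balanced_transition_matrix()` form a benchmark condition for the learning
experiments: contrasts are exaggerated and the five stages are made near
equally likely with moderate (0.75) persistence, so that chance-level
agreement on shuffled labels sits near zero while the sequence structure
remains learnable. What passing tests on this synthetic world shows is that
the pipeline is implemented correctly and can learn stage-conditional
structure when it is present; it does not show clinical-grade accuracy on
real PSG, where stage differences are far subtler, artifacts abound, and
inter-rater disagreement caps achievable agreement.

## Numerical choices and edge cases

* All Butterworth filters are order 2 per band edge and applied
  forward-then-backward (`signal::filtfilt`) for zero net phase shift;
  phase integrity is what λ measures, so the filters must not skew it. The
  effective magnitude response is the squared single-pass response. Edge
  transients of a few seconds exist at record boundaries; interior epochs
  are unaffected.
* The RRI outlier screen is a deterministic surrogate for visual
  inspection: tachogram points outside 300–2000 ms, or differing more than
  30% from the median of the five preceding accepted intervals, are
  dropped. Points (not later beats) are removed, so one artifact or a
  signal gap cannot cascade.
* The wavelet uses 128 log-spaced analysis frequencies across 0.05–0.6 Hz
  (grid spacing ≈ 0.005 Hz near 0.25 Hz, comfortably inside the 0.01 Hz
  recovery tolerance); complex Morlet with bandwidth 1.5 and center
  frequency 1.0 in normalized units; PSD peaks tie-break toward the lowest
  frequency; the 20 s analysis window is centered on each 10 s parameter
  window and truncated at record edges. An all-zero window yields a
  missing `f_R`, which carries the last valid estimate forward (band
  center 0.325 Hz if the night starts missing).
* The λ summation runs over exactly the N trailing samples ending at the
  window's end (the printed index range `j = k−N..k` over divisor N is
  internally inconsistent by one sample; the N-sample convention is chosen
  and stated, not asserted as anyone's intent). Positions earlier than N
  samples use the available shrinking window.
* The RSA band uses the night-median dominant respiratory frequency, so a
  single zero-phase filter serves the whole night; the ±50% band is wide
  enough to cover normal within-night drift.
* Epoch aggregation order: median filter first (6-point window, shrinking
  at the series edges), then the per-epoch mean of the six filtered window
  values — the two published smoothing sentences composed in the order
  they are stated.
* Epochs are half-open `[30k, 30(k+1))` seconds with 0-based indices;
  10 s windows are `[5k, 5k+10)` with the last window truncated at the
  record end, giving exactly 6 windows per epoch and a feature row count
  always equal to the hypnogram length.

## Problem sizes used by the packaged experiments

The scaled study that the tests and `scripts/acceptance.R` run end-to-end:
12 subjects × 2 h nights under the separated benchmark profiles, features
extracted as above, full leave-one-subject-out cross-validation with
`fast_stager_config()`, the label-shuffled control computed on the epochs
pooled across folds (200 permutations), and sleep-parameter agreement on
the per-fold predictions. Single-stage recovery nights are 20 min (HR/RR),
60 min (movement counts) and 10 min (λ jitter ladder). These sizes were
chosen as the smallest at which every property under test is comfortably
away from its noise floor.

## Known limitations

* The biLSTM runs on the CPU in base R; the full-scale 3×128 configuration
  on a 123-night cohort is out of reach at desk scale (the architecture is
  identical, only the sizes differ in the fast profile).
* The LOOCV protocol's double use of the held-out night (early stopping and
  evaluation) is faithful to the stated scheme but optimistic.
* The generator does not simulate raw ECG/EEG/EOG, oximetry, apnea events
  or AASM microstructure (spindles, arousals); apnea severity exists only
  as a per-subject covariate label.
* Sleep-latency estimation inherits the single-epoch onset rule; on real
  data SL is known to be biased when early epochs are misclassified.
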