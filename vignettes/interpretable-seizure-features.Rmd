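---
title: "Interpretable five-feature EEG seizure detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable five-feature EEG seizure detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmark)
```

## The problem and the model

Epileptic EEG differs from background EEG in two complementary ways.
First, it carries characteristic transient waveforms: *spike waves*
(20–70 ms, amplitude above 50 µV) and *sharp waves* (70–200 ms, roughly
100–200 µV). Second, the abnormal synchronous discharge of large neuron
populations makes the signal *less complex* — more regular and more
predictable — than background activity.

`eegmark` turns these two observations into exactly five window-level
features:

* **SpikeE**, **SharpE** — pathological wave energy: the summed squared
  sample values over the supports of detected spike and sharp-wave events
  (µV²). These encode transient morphology.
* **HFD** — Higuchi fractal dimension, a curve-length-scaling estimate of
  signal roughness (≈ 1 for smooth curves, ≈ 2 for white noise).
* **PE** — permutation entropy, the Shannon entropy (nats) of the ordinal
  pattern distribution of delay-embedded subsequences. Both complexity
  measures *fall* during seizures.
* **DFI** — dynamic feature increment: the per-window sum of absolute first
  differences of the four (normalized) base features, capturing how sharply
  the feature profile moves between adjacent windows, i.e. state-transition
  dynamics.

A recording is split into 256-sample windows with 50% overlap; each window
becomes one five-feature row; classical classifiers (SVM, decision tree,
random forest, KNN, XGBoost) are evaluated over those rows under a
leakage-safe recording-stratified cross-validation; exact Shapley values
attribute each prediction to the five features.

## The wave detector

`wave_events()` finds every strict local maximum and walks outward while
samples strictly decrease to the nearest flanking troughs (window edges
count as troughs so overlap-induced boundaries do not lose events).
For each peak triple:

* **duration** = trough-to-trough width in ms. "Wave width" has no single
  operational definition for transients; trough-to-trough width is
  computable directly from the peak triple and matches how transient
  widths are measured clinically.
* **amplitude** = peak minus the mean of the two trough values, a
  prominence-like measure robust to baseline drift (an absolute-value
  amplitude would make the detector sensitive to slow offsets).

A triple is accepted as the first matching class, spike checked first.
Deterministic boundary decisions worth knowing:

* The shared 70 ms boundary belongs to **sharp** waves: the spike duration
  interval is right-open, `[20, 70)` ms.
* Amplitude intervals are closed (`[50, ∞)` for spikes, `[100, 200]` µV for
  sharps). The sharp ceiling is configurable to `Inf` because the clinical
  range is approximate.
* When two accepted events of one class share a boundary trough (adjacent
  peaks separated by a single local minimum), the later event's *energy
  support* starts one sample later so no sample is counted twice; duration
  and amplitude are still measured trough-to-trough.
* Only upward transients are detected by default; `detect_negative = TRUE`
  additionally runs the detector on the sign-flipped signal.

Amplitude thresholds are in microvolts, so raw ADC units must be calibrated
(`calibration` argument of the readers); `read_bonn_text()` warns when
`calibration = 1` is left in place.

No spectral gate is applied: the frequency ranges sometimes quoted
alongside the duration ranges are their reciprocals, not an independent
criterion.

## Nonlinear features: parameters and defaults

Permutation entropy needs an embedding dimension `m` and delay `tau`.
Defaults are `m = 3`, `tau = 1`: a 256-sample window yields `M = 254`
embedded vectors against `3! = 6` patterns — comfortable sampling — whereas
`m = 4` (24 patterns) already strains a window this short. Ties between
equal sample values are broken by original index (stable), which keeps the
estimator fully deterministic; a constant run therefore counts as
ascending. The entropy uses the natural logarithm and is emitted
unnormalized (nats); `normalized = TRUE` divides by `ln m!` when a
`[0, 1]` scale is preferred.

The Higuchi estimator uses `k_max = 10` by default: with 256-sample
windows, larger scales leave too few points per decimated subsequence. The
slope of `ln` mean curve length against `ln k` is fitted by *unweighted*
ordinary least squares over `k = 1..k_max` — the simplest defensible
choice absent a reason to weight scales. A constant window has zero curve
length at every scale; `higuchi_fd()` returns 0 with a warning rather than
erroring, so a flat (e.g. clipped-out) window cannot abort a batch run.

## DFI: conventions and leakage

Two readings of "normalize, take absolute values, and sum the first-order
differences" are possible: the sum of per-feature absolute differences
(`sum_abs`) or the absolute value of the summed signed differences
(`abs_sum`, under which opposite feature movements cancel). The prose
ordering — absolute value per feature, then sum — selects `sum_abs`, which
is the default; the alternative sits behind `dfi(convention =)`.

Likewise, the increment could be aggregated over time (one value per
recording) or over features (one value per window). Because DFI is used as
a per-window classifier input, the per-window reading is implemented: at
window `t`, DFI is the sum over the four features of
`|norm(t) − norm(t−1)|`, with DFI = 0 at each recording's first window.
Differencing never crosses recording boundaries.

Normalization bounds are min–max bounds *fitted on training-fold windows
only* and applied to test folds with clipping to `[0, 1]` — so a test value
outside the training range cannot leak information backwards, and DFI is
bounded in `[0, 4]`.

## Evaluation protocol

`build_fold_plan()` assigns whole recordings to folds, stratified by
class, so windows from one recording never straddle the train/test split —
overlapping windows from a single recording are heavily correlated, and
splitting them would inflate every metric. Per fold, the min–max scaler
and the DFI bounds come from training rows only. Metrics are averaged over
the ten test folds; confusion matrices are summed.

Classifier hyperparameters are fixed, with no tuning: SVM with RBF kernel
and `C = 1`; `maxdepth = 10` for the decision tree; 100 trees with depth
cap 10 for the random forest (via `ranger`, which exposes `max.depth`) and
XGBoost; five neighbours for KNN. Everything else is the delegated
library's default. KNN is implemented in-package with a deterministic
stable distance tie-break because `class::knn` breaks ties randomly and
does not expose full per-class vote fractions; all five classifiers thus
share one `predict(type = "prob")` interface.

Binary metrics take the ictal/seizure class as positive (detected by name,
overridable). Multiclass metrics are macro-averaged one-vs-rest with equal
class weight. Ratios of the form 0/0 (e.g. precision with no positive
predictions) are defined as 0 with a warning. Note that macro one-vs-rest
*accuracy* of a three-class chance classifier is ≈ 0.56, not 1/3; the
label-permutation null check therefore uses plain overall accuracy.

## Exact Shapley attribution

With five features the `2^5 = 32` coalition values are enumerated exactly —
no sampling, bit-identical across runs — so the local-accuracy identity
(base value plus attributions equals the model output) holds to
floating-point precision by construction, and the dummy/symmetry/linearity
axioms are testable directly. The value function is *interventional*:
features in the coalition take the instance's values, the rest take values
from an explicit background table (typically the training fold, subsampled
to ≤ 256 rows with a seed); this is the standard convention for tree
models and is exactly computable here. For multiclass models the explained
output is the *probability* of the target class (default: the model's
predicted class) — probabilities, not margins, because per-class
probability attributions compare cleanly across classifiers.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` builds labeled recordings as colored-noise background
(power ∝ 1/f, standardized), plus a fixed-frequency oscillation carrying a
`regularity` fraction of the variance, plus non-overlapping raised-cosine
(Hann) pulses at Poisson times. The Hann pulse was chosen because its
trough-to-trough width and peak amplitude are controlled analytically, so
every injected event's ground-truth class (under the same
duration–amplitude rules the detector applies) and exact energy are
logged — which is what makes closed-loop detector tests possible.

Default state profiles (all configurable): interictal 0.05 spikes/s and
regularity 0.2; preictal 0.5/s and 0.4; ictal 2/s and 0.7 with event
amplitudes shifted up (110–180 µV spikes, 150–200 µV sharps) and a larger
background (30 µV vs 15 µV standard deviation). Sharp-wave rates equal the
spike rate of each state. Each recording draws its own realization of
regularity (± 0.2), oscillation frequency (5 ± 2 Hz) and background scale
(± 20%): recordings, not windows, differ — the inter-recording
heterogeneity that makes recording-stratified evaluation necessary, and
the reason per-state complexity distributions are wide and overlapping
rather than cleanly separated. These values were chosen so that the
qualitative structure the method assumes holds robustly: energies highest
in ictal and lowest in interictal, complexity the reverse with preictal
intermediate, and the pathological family the most discriminative of the
three. They are fixture parameters, not physiological claims.

What the generator does **not** emulate: real spike morphology (asymmetric
rise/decay, after-going slow waves), spike-and-wave complexes, artifacts
(muscle, eye movement, electrode pops), non-stationary background,
multichannel structure, or genuine preictal dynamics. A pipeline that
passes the synthetic tests is verified as *correctly implementing the
method*; performance numbers on synthetic data say nothing quantitative
about clinical EEG.

## Numerical and degenerate-input choices

* Trailing partial windows are discarded, not zero-padded: fixed-length
  windows keep the feature definitions uniform.
* Degenerate min–max bounds (`max ≤ min`) map a feature to all zeros with
  a warning instead of dividing by zero.
* Ordinal ties: earlier index first, everywhere.
* The generator requires even pulse supports so the sampled pulse has a
  unique strict maximum; widths are rounded to the nearest even number of
  samples.
* Seeds: dataset generation takes one master seed; the fold plan, each
  fold's classifier, and permutation checks derive their seeds from the
  run seed by fixed offsets, all below 2³¹.

## Problem sizes used by the tests

The full-scale testing study uses the generator defaults: 3 states × 50
recordings of 23.6 s at 173.61 Hz (4097 samples, 31 windows each,
4650 windows total) — large enough for 10-fold recording-stratified CV
with five recordings per state per fold, and comfortably reproducible on a
single CPU. Detector–oracle equivalence uses 200 random windows of ≤ 64
samples against an independent brute-force implementation; the closed-loop
check uses ≥ 200 injected ground-truth events on zero background.

## Known limitations

* The MAT reader handles real numeric arrays in uncompressed (and, where
  `memDecompress` can inflate them, zlib-compressed) MAT v5 elements —
  sufficient for one-vector-per-file EEG segment corpora, not a general
  MAT parser.
* The detector has no notion of polyspikes or spike-and-wave complexes;
  overlapping transients merge or shadow each other.
* Energy features are calibration-dependent; comparing energies across
  datasets with different (or unknown) ADC scales requires care — the
  cross-dataset mode normalizes per training set, which absorbs scale but
  not shape differences.
* Preprocessing is limited to an optional zero-phase Butterworth band-pass
  (`bandpass_filter()`, 0.5–70 Hz, 4th order, off by default); no artifact
  rejection is provided.
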