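---
title: "Quality-guided channel selection for non-invasive fetal ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-guided channel selection for non-invasive fetal ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fecgsqa)
```

## The model

Non-invasive fetal electrocardiography records the fetal heart's electrical
activity through electrodes on the maternal abdomen. Each abdominal lead is
a mixture of a large maternal ECG (mECG, typically tens to hundreds of
microvolt), a fetal ECG (fECG, often an order of magnitude smaller, and
strongly dependent on the electrode's position relative to the fetus),
sub-hertz baseline wander, 50 Hz powerline interference and broadband
noise. Because fetal position is unknown and changes over time, only a
subset of the leads carries usable fetal content at any moment.

`fecgsqa` frames lead triage as binary classification of *raw* (only
high-pass filtered) 5-s segments. Sixteen scalar signal quality indexes
(SQIs) summarise each segment's time- and frequency-domain character, and a
bagged decision-tree ensemble maps them to informative / non-informative.
Working on the raw signals keeps the method independent of any particular
extraction algorithm and cheap enough for wearable monitors: the costly
extraction step then runs only on the selected channels.

### Preprocessing

Channels are resampled (polyphase, rational factor) and high-pass filtered
with a causal Butterworth filter before segmentation. Two presets exist:

* `train` — 500 Hz, 1 Hz cut-off, 4th order: the light preprocessing used
  for feature extraction and training. The cut-off is deliberately the
  lowest reasonable value; powerline and high-frequency noise are left in
  the signal so the classifier learns to recognise them (no notch filter,
  which would bite into the fECG band).
* `ninfea` — 512 Hz, 3 Hz cut-off, 5th order: a more aggressive variant
  for recordings with pronounced baseline wander.

Filtering is single-pass (causal), matching the real-time motivation; the
whole channel is filtered before segmentation so segment boundaries see no
filter transients. Segments are consecutive, non-overlapping windows of
exactly `round(5 * fs)` samples starting at sample 0; a trailing remainder
is discarded. Overlap would only manufacture correlated training rows.

### The sixteen quality indexes

Band powers (`pband1`–`pband5`, in [0.5–10], [10–20], [20–48], [48–52] and
[52–100] Hz) are mean Welch PSD densities over the band bins, with both
band edges inclusive. The PSD uses 1-s Hann windows with 50 % overlap —
the estimator itself is a free choice, and this one balances variance
against the 1 Hz resolution the narrow [48–52] Hz powerline band requires.
The two ratio features (`pSQI` = P[5,15]/P[5,45], `basSQI` =
P[0,3]/P[0,100]) use *integrated* (summed) bin powers instead, so the
unequal band widths cancel identically in numerator and denominator.
`seSQI` is the Shannon entropy of the normalised PSD divided by
`log(n_bins)`; `bas_pow` is the standard deviation of a 1-s moving-average
baseline (window forced odd, edges reflected); `ss` is the maximum absolute
first difference scaled to µV/s; `HA`/`LA`/`stdSQI` are the signed extremes
and the standard deviation; `kSQI`/`sSQI` are the population
(biased) kurtosis and skewness, with kurtosis non-excess so Gaussian noise
scores 3 and a clean spiky ECG well above 5; `complexity` is the Hjorth
ratio mobility(Δx)/mobility(x), equal to 1 for a pure tone and larger for
broadband signals. Population estimators are used throughout for
consistency with the Gaussian-reference interpretation of the moments.

Zero-variance (or otherwise degenerate) segments never crash the pipeline:
their moment and ratio features are recorded as 0 with a `degenerate` flag,
and the classifier maps flagged rows to non-informative by construction.

### Labelling and balancing

A channel is *informative* when the signal-to-noise ratio of its fECG is
strictly above 5 dB. For synthetic training data the generator's
ground-truth SNR is the default labeller — it is exact and removes any
dependence on a specific extraction method. For real data the package
provides a template-based surrogate: 100-ms windows centred on the
annotated fetal R-peaks are averaged into a beat template, and the SNR is
the template power over the mean beat-to-template residual power. Because
non-informative channels dominate real recordings, the majority class is
randomly downsampled to a balanced table before training.

### Feature ranking and selection

The greedy minimum-redundancy maximum-relevance ranking uses the
*difference* (MID) criterion: the first feature maximises the mutual
information with the label, every later pick maximises
`MI(f, y) − mean MI(f, selected)`. MID avoids the division instabilities of
the quotient form; both are classical. Mutual information is a plug-in
estimate on 10 equal-frequency bins — robust to the heavy-tailed SQI
distributions. A feature's raw score is its criterion value at selection
time floored at 0; per cross-validation training split the scores are
min–max normalised to [0, 1], summed across the 100 splits of the 10×10
scheme, and the smallest descending-relevance prefix reaching 80 % of the
total is selected. Exact ties in the criterion are broken by the canonical
feature order, with a small numeric tolerance so that floating-point
summation order cannot flip a tie.

### Classifier

A bagged ensemble of 100 CART trees (Gini impurity), each grown on a
bootstrap resample and limited to ten decision splits, mirrors a stock
bagged-tree configuration and is deliberately not tuned. The number of
features tried per split defaults to √16 = 4 (`"sqrt"`), with `"all"`
available. The prediction score is the fraction of trees voting
informative; a 0.5 tie resolves to non-informative, because a false
positive costs downstream extraction compute while a false negative merely
drops one of several redundant leads. A channel is selected when a strict
majority of its 5-s segments is predicted informative. Cross-validation is
10-time 10-fold with label-stratified partitions; per partition the five
metrics (Acc, TPR, TNR, PPV, F1) are computed from the confusion counts,
and any metric with a zero denominator is excluded from the medians rather
than forced to zero.

### Extraction, detection, scoring

The maternal ECG is cancelled by exponentially weighted recursive least
squares over a regressor that concatenates 20-sample delay lines of three
thoracic reference leads (60 weights), with forgetting factor λ = 0.999.
The implementation propagates the upper-triangular square-root factor with
Givens rotations (QRD-RLS) — numerically stable, and verified in the tests
to agree with a covariance-form RLS to 10⁻⁶ and, at λ = 1, with the
regularised normal-equation solution. The triangular factor is initialised
to 0.01·I; the first 10 × 20 = 200 samples are flagged as start-up
transient and excluded from SNR estimation and detection scoring. One
practical property surfaced by the tests: with a ~1000-sample memory and 60
adaptive weights, the filter's misadjustment absorbs roughly a tenth of the
energy of whatever the references cannot explain — the extracted fECG is
attenuated but remains strongly correlated (≈ 0.94) with the true fetal
component, and R-peak locations are unaffected.

The fetal QRS detector is a max-search: the polarity whose extrema have the
larger median magnitude is taken as upright, and peaks are the samples that
are maxima of the polarity-corrected signal within ± w samples,
w = round(0.5 · fs / expected rate) with 2.2 Hz (≈ 132 bpm, mid-fetal
range) as the default expected rate. It runs on the raw polarity-corrected
amplitude, not a squared transform, preserving the max-search character.
Detections are matched to reference peaks one-to-one, greedily by ascending
time difference, within a ± 50 ms tolerance ("50-ms tolerance window" could
also be read as ± 25 ms; ± 50 ms matches common fetal-ECG challenge
practice, and the tolerance is a parameter). With fetal beats at least
~370 ms apart and a 50 ms tolerance, greedy nearest-first matching is
provably optimal; the tests verify it against an exhaustive enumeration
oracle. Counts are micro-averaged (summed) over a recording's channels
before metrics, giving one value per recording per condition; conditions
are compared with Kruskal–Wallis and paired Wilcoxon signed-rank tests,
Bonferroni-corrected over the pairwise family at α = 0.05.

## The synthetic generator

`ecg_waveform()` builds each beat from five Gaussian bumps (narrow Q, R, S;
broad P and T), with QRS width ≈ 40 ms for the fetus and ≈ 90 ms for the
mother, and RR intervals jittered by truncated (± 3σ) multiplicative
Gaussian noise. This is far simpler than a full dynamical ECG model but
exercises every SQI: spiky QRS trains are leptokurtic, band powers
concentrate in the right ranges, and the beat templates are deterministic
given the seed. `generate_recording()` mixes per channel: maternal waveform
× channel gain, fetal waveform × per-channel amplitude, a baseline
sinusoid below 1 Hz, 50 Hz powerline interference (fixed at the European
mains frequency, which the [48–52] Hz band targets) and white noise;
reference leads carry only the maternal component plus small noise. The
ground truth records both R-peak trains and each channel's *true fetal
SNR*: fetal power over everything-else power, computed after the same 1 Hz
high-pass the pipeline applies, so ground-truth labels match what the
classifier sees.

`study_channel_profile()` models electrode proximity: about a quarter of
the abdominal channels are fetal-proximal (fetal R amplitude 30–50 µV,
maternal gain 0.02–0.10) and the rest maternal-dominated (fetal 0–5 µV,
maternal gain 0.45–1.2), with 2 µV noise and 2 µV powerline at the study
settings. These values were fixed once so that roughly 25 % of channels
exceed the 5 dB threshold with a realistic spread of borderline cases, and
are not revisited. What the generator does **not** model — fetal movement,
electrode-contact artifacts, uterine EMG, non-stationary noise — bounds
what the tests show: passing them demonstrates the pipeline's internal
correctness and the *relative* benefit of channel selection, not clinical
performance levels. Cross-validated accuracies near 99 % on synthetic data
are an artifact of the generator's separability, not a clinical claim.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale cohorts chosen to
exercise every code path with stable statistics: training on 10 simulated
recordings (24 abdominal + 3 reference channels, 30 s, ≈ 1400 segment rows
before balancing) and evaluating detection on 20 disjoint recordings of
30 s. The oracle suites run the 16 SQIs against naive direct-definition
implementations on 100 random segments, the greedy mRMR against exhaustive
recomputation on 50 small tables, the QR-form RLS against the
covariance-form recursion and the normal equations, and the peak matcher
against exhaustive optimal matching on ≤ 8-peak instances.

Numerical details that matter: second-order IIR filtering uses the
`signal` package's direct-form implementation (both presets are verified
stable); the Welch PSD normalises to a one-sided density so Parseval holds
within the Hann window's variance; equal-frequency binning collapses
duplicated quantiles (a constant feature has one bin and zero mutual
information); mRMR raw scores are floored at zero before normalisation so
relevance is non-negative; `-Inf` SNR (zero fetal amplitude) and `+Inf`
(noise-free fetal-only channel) are legal values, and labelling treats the
threshold strictly (5.00 dB is non-informative). All stochastic components
(generator, balancing, bootstrap, fold assignment) are seeded; identical
seeds give bit-identical recordings, models and cross-validation results.

## Known limitations

* The generator's maternal/fetal mixing is instantaneous and linear; real
  volume conduction adds propagation effects the adaptive filter handles
  only approximately.
* The template-based SNR estimator requires ≥ 3 annotated beats and
  assumes a stable beat morphology over the analysed stretch.
* The detector has no amplitude gate: on signals with long beat-free
  stretches it will promote noise maxima to peaks (visible as a single
  trailing false positive on short synthetic trains).
* Channel-level decisions use a strict majority of 5-s segments; a
  recording barely longer than 5 s rests on very few votes.
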