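---
title: "Screening sleep apnea from wearable PPG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening sleep apnea from wearable PPG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneascreen)
```

## The problem

Apnea — a pause in breathing of roughly ten seconds or more during sleep —
perturbs autonomic control of the heart and, with a lag of a few seconds,
depresses arterial oxygen saturation. Both effects are visible to a wearable
optical sensor: the photoplethysmogram (PPG) records beat-to-beat pulse
timing and amplitude, and a dual-wavelength (red/infrared) sensor yields
SpO2. `apneascreen` turns a night of single-channel PPG plus optional SpO2
into per-minute apnea decisions and an apnea–hypopnea index (AHI).

The pipeline has six stages: preprocessing, multiscale sample entropy,
wavelet pulse-peak detection, PRV feature extraction, random-forest window
classification, and SpO2-gated event reporting. This vignette documents the
model behind each stage, the tunable parameters, and the design decisions
taken where the problem is genuinely open.

## Preprocessing

Three noise classes dominate wearable PPG: power-line pickup, high-frequency
electromyographic (EMG) interference from poor skin contact, and
low-frequency baseline wander from motion and perfusion changes.

* **Baseline removal.** The baseline is estimated by a centered running
  median of 2.5 s (2.5·N samples at sampling rate N) — long enough to
  straddle several pulse periods, so the median tracks the wander and not
  the pulses — and subtracted. Edges are handled by reflection, which avoids
  the bias of constant padding; both medians are verified against a naive
  sort-based oracle in the tests.
* **Despiking.** `median_denoise()` implements the same exact running-median
  contract with a default window of 2 s. In the composite pipeline
  `preprocess_ppg()` the despiking window defaults to 0.15 s instead: a
  running median only preserves features wider than about half its window,
  so a multi-second median would annihilate the ~1 Hz pulse band itself,
  while a sub-pulse-width median removes isolated bursts and leaves the
  waveform intact. This is a deliberate package decision; the standalone
  function keeps the longer default for users who want the aggressive
  variant.
* **Lowpass.** A 10th-order Chebyshev type II IIR lowpass with the passband
  edge at 4.8 Hz, at most 1 dB passband deviation, and at least 60 dB
  stopband attenuation. The family is chosen because its free parameter set
  (order, attenuation, edge) matches the published specification exactly;
  the stopband edge — the first frequency at which attenuation reaches
  spec — is solved numerically by root-finding on the realized frequency
  response and reported in the design object (6.5 Hz at 100 Hz sampling).
  A lighter 5th-order / 40 dB variant is provided for on-sensor use. Delay
  compensation drops the first M/2 samples (M = order). Note that the true
  group delay in the pulse band is larger (~0.13 s); this residual constant
  lag is harmless downstream because every extracted feature is
  time-shift-invariant.
* **Windowing.** Analysis windows are 60 s, slid by 1 s by default
  (`segment_windows()`); a window inherits the apnea label of the minute
  containing at least half of it. The screening pipeline `diagnose()` uses a
  60 s stride by default so that decisions align with the one-minute label
  unit; the 1 s slide remains available through its arguments.

## Multiscale sample entropy

SampEn(m, r) of a series is `-ln(A/B)`, where `B` counts pairs of length-m
templates within Chebyshev distance r (self-matches excluded) and `A` the
subset still matching at length m+1. Both counts run over the first `N - m`
template positions, so `A <= B`, a constant series gives exactly 0, and the
value is non-negative whenever defined. If no pair matches at either
dimension the value is undefined and returned as flagged `NaN`; downstream,
flagged entries are imputed with the column median of the finite values and
recorded in an imputation mask, so no silent guessing occurs.

Defaults are the standard SampEn convention, `m = 2` and `r = 0.2` of the
series SD; the tolerance is referenced once to the SD of the *original*
series and reused at every scale, the common multiscale convention, so that
coarse-graining (which shrinks variance) does not silently tighten the
match criterion.

Two coarse-graining schemes are provided. The classical one averages
non-overlapping blocks of τ samples, discarding up to τ−1 tail samples. The
overlap scheme slides a τ-sample window by `max(1, round(τ/2))` (ties round
up for odd τ — "50% of the window" made concrete), keeping every full
window; it never yields a shorter series than the block scheme and loses no
tail data whenever the step divides L−τ. Scales run from 1 to 15 by default
and the scale-1 entry is identical for both schemes (the raw series). The
full 15-entry vector is used as the entropy feature block; a subset can be
selected downstream by the embedded feature selection.

The pair counting is an O(N²) loop in C++; the test suite checks it to
1e-10 against an independent brute-force oracle built from embedding
matrices and `stats::dist`.

## Pulse-peak detection

The detector operates on the detail coefficients of an undecimated
(à-trous) quadratic-spline wavelet transform at scale 2³, computed with the
classical smoothing filter (1,3,3,1)/8 and detail filter (2,−2). These
coefficients behave like a smoothed derivative: each pulse generates a
positive modulus maximum on its rising edge, a negative one on the falling
edge, and a zero-crossing at the peak. The transform's group delay (6.5
samples) is corrected exactly, so crossings map onto input sample indices;
on noiseless pulses the located peaks are exact.

Detection proceeds in the published order: threshold the extrema
(`thp = c·RMS` of the positive coefficients, `thn = −c·RMS` of the negative
ones, `c = 1.5` by default — the initialization is an extrapolation, since
no rule is published), pair a positive extremum with the following negative
one only if the coefficient path between them is monotone (a 10%
backtracking tolerance absorbs noise ripple; unpairable extrema are orphans
and removed), interpolate the zero-crossing, enforce a 200 ms refractory
period, and finally re-search any inter-peak gap longer than 1.5× the mean
peak-to-peak interval with thresholds relaxed to 4/5 of their values (the
search stays inside the gap, excluding the flanking refractory zones, and
the original thresholds are restored afterwards; one pass, so termination is
trivial). Because the scale-2³ wavelet is itself a band-pass smoother, the
detector tolerates EMG-band noise directly: on synthetic recordings with
moderate EMG noise it holds F1 ≥ 0.95 against ground-truth beat times.

## PRV features, selection, classification

From each window's peak train: pulse rate, mean/SD/median peak-to-peak
interval (ms), NN50 (successive interval differences strictly exceeding
50 ms), pNN50 (NN50 over the number of successive differences, reported as
a fraction in [0, 1]), and SD/mean/median of peak amplitudes. Windows with
fewer than three peaks are degenerate: the rate is kept, dispersion features
are flagged and imputed at assembly time. The combined feature vector is 15
entropy + 9 PRV = 24 columns in a fixed, serialized order.

Feature selection is embedded: a random forest ranks columns by Gini
importance and a threshold (default: the mean importance) keeps the strong
ones. Selection is fitted on training data only.

The window classifier is a 500-tree random forest (deterministic under a
fixed seed); SVM, k-nearest-neighbour and gradient-boosted-tree comparators
run behind the same interface, and `benchmark_models()` scores all of them
on a stratified 70/30 split with Se, Sp, Acc and wall time. The split policy
is the package's own choice — no split protocol is published for the
original benchmark, which also used a clinical database that this package
does not ship; the corpus results here therefore verify the pipeline's
behaviour, not the published clinical numbers.

## SpO2 and comprehensive gating

Saturation derives from the dual-wavelength ratio-of-ratios
`R = (AC_red/DC_red)/(AC_ir/DC_ir)` (per second: DC = mean, AC = SD). The
definitional formula `SpO2 = C_HbO2/(C_HbO2+C_Hb)·100` is not computable
from intensities alone, so the conventional empirical linear calibration
`SpO2 = 110 − 25R` closes the gap (configurable; the generator inverts the
same map, and the round trip is exact to within 1% wherever AC is present).
Seconds with absent AC or non-positive DC are flagged invalid rather than
fatal.

Desaturation events are maximal runs below 90%. An event is attributed to a
sensor artifact — not to apnea — when at least half of its seconds carry
quality flags (probe loosening, dropout, AC collapse); artifact events
produce user-visible warnings. The comprehensive decision per window is:
PPG-positive **and** overlapping a pathological desaturation → confirmed;
overlapping only artifact drops → rejected with a warning; SpO2 present but
showing no desaturation → unconfirmed; no SpO2 channel at all → accepted
with a low-confidence note. Confirmed windows whose spans touch merge into
events (an event needs ≥ 10 s of positive coverage, the minimum apnea
duration); AHI = events/hour with the standard severity cutoffs
(5/15/30).

## The synthetic generator

The generator emulates exactly what the pipeline must be sensitive to:
quasi-periodic pulses (two-Gaussian systolic + dicrotic template, amplitude
jitter 3%), beat-interval jitter (default SD 30 ms), apnea episodes that
multiply the interval SD by 3 and damp the amplitude to 0.8 (no generative
apnea model is published; these factors were fixed once so that apneic
minutes are statistically separable, which is all the classifier contract
requires), 50 Hz power-line pickup, band-limited (>10 Hz) EMG noise, a
sub-0.5 Hz random-walk baseline, SpO2 desaturations (5 s onset delay,
0.5 %/s fall to an 85% nadir, 15 s recovery — typical clinical shapes;
episodes of ≥ ~20 s cross the 90% threshold), and probe-artifact drops with
ground-truth flags. The default sampling rate is 100 Hz (no device rate is
published; 100 Hz is conventional for pulse oximetry modules and
configurable). Fixed seeds give bit-identical recordings.

What the generator does *not* emulate: real hemodynamics, respiration
coupling, motion artifacts with realistic spectra, ectopic beats, or the
morphology variation across subjects and sensor sites. Passing tests on
this corpus therefore demonstrate internal correctness and sensible
behaviour of every stage — not clinical performance. Numbers published for
clinical recordings (accuracy near 92% on a polysomnographic database) are
out of reach of a synthetic corpus by construction and are not claimed.

## Problem sizes and numerical choices

The shipped corpus is 90 independent 60 s windows (45 normal, 45 apneic) at
100 Hz; the end-to-end demonstration screens a 1-hour recording with five
planted episodes. These sizes give stable classifier metrics and exercise
every code path while keeping a full run of the suite in the
low-minutes range. Other numerical policies collected in one place:

* running-median edges: reflection; exact oracle equivalence enforced.
* entropy tolerance at degenerate SD 0: machine epsilon (constant series
  still give SampEn 0).
* undefined entropies / degenerate PRV windows: flagged `NaN`, column-median
  imputation, mask retained; prediction-time imputation reuses the
  *training* medians stored in the model.
* zero-crossing localization: linear interpolation, rounded to the nearest
  sample after alignment correction.
* tie at the window-label boundary (window straddling two minutes equally):
  the earlier minute wins (the ≥ 50% rule).
* severity at the cutpoints: 5 and 15 and 30 map to mild/moderate/severe
  boundaries as `<5` none, `5–15` mild, `15–30` moderate, `>30` severe.

## Known limitations

* The R→SpO2 calibration is the textbook linear map; real sensors need
  empirical per-device coefficients.
* Only the univariate entropy of the single PPG channel is computed;
  red/infrared channels are used for oximetry, not joint entropy.
* Apnea subtypes (obstructive/central/hypopnea) are not distinguished.
* Event counting merges adjacent positive minutes; with sparse 60 s strides
  two distinct apneas inside one minute count once.
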