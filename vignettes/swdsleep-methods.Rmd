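---
title: "Methods: spike-wave detection, sleep scoring and the synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-wave detection, sleep scoring and the synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdsleep)
```

This vignette explains the models behind `swdsleep`, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data tests
do and do not establish about real recordings.

## The signals and their containers

A `Recording` holds a channels-by-samples matrix in microvolts with one
sampling rate (default 250.4 Hz, a common telemetry rate), per-channel roles
(EEG/EMG), and two clock anchors: the start time of the recording and the
lights-off time (default 19:00, 12:12 cycle). Time is always decimal seconds
from recording start; intervals are half-open `[start, end)`; epochs are
indexed from 0. These conventions make joins between event tables and epoch
grids unambiguous. A `Hypnogram` is the per-epoch label sequence over
`WAKE/NREM/REM/SWD/UNSCORED` on a 5-s grid (1-s grid for detection); an
`EventTable` is a sorted, non-overlapping set of SWD intervals.

## Spectral estimation

All band powers come from Welch's method: mean of Hann-windowed one-sided
periodograms, density-scaled so that the integral of the PSD over
`[0, fs/2]` equals the signal variance (checked to 5% on white noise in the
test suite). Defaults are 2-s windows with 50% overlap, giving ~0.5 Hz
resolution — enough to separate a 5–10 Hz fundamental from its first
harmonic inside a 5-s epoch. Band powers integrate the PSD by the trapezoid
rule with linear interpolation at the band edges, which makes band power
exactly additive over a partition of a band.

Band edges are configuration, not dogma: delta `[1,5)`, theta `[5,10)`,
sigma `[10,16)`, beta `[16,30)`, gamma `[30,48)` Hz. Theta is deliberately
set to coincide with the SWD fundamental range, and gamma stops below 50 Hz
mains. Trailing partial epochs are dropped, never zero-padded, to avoid
biased tail spectra. The zero-phase band-pass filter used for delta-trace
display is a forward–backward Butterworth high-pass/low-pass cascade
(order 4 per edge); the cascade form is numerically robust for narrow
low-frequency bands at a 250.4 Hz rate, where a single 8-pole band-pass
polynomial is ill-conditioned.

## SWD detection by harmonic spectral peaks

A spike-and-wave complex is a sharp spike plus a slow wave repeated at a
fundamental f0 between 5 and 10 Hz; its Fourier series necessarily contains
f0 and strong harmonics. The detector therefore flags a 1-s epoch when all
three hold:

1. **Fundamental**: a local PSD maximum at f0 in `[5, 10]` Hz whose ratio to
   a running-median spectral baseline (half-width 2 Hz, robust to the 1/f
   slope) is at least 3, and which is the global PSD maximum over 1–48 Hz.
   The dominance condition reflects that during a discharge the fundamental
   dominates the whole spectrum; without it, chance peaks in delta-dominant
   NREM epochs inflate the false-positive rate.
2. **Harmonic**: a local maximum within ±1 Hz of 2·f0 with baseline ratio at
   least 2.
3. **Amplitude**: epoch RMS at least twice the recording's *median* epoch
   RMS. The threshold is relative, so detection is invariant to overall
   gain; the test suite asserts identical output after scaling a recording
   by 1000.

Each 1-s epoch's PSD averages the three 1-s Hann windows centred on it
(starts at t−0.5, t, t+0.5 s). A single 1-s periodogram has chi-squared(2)
bin noise, and a ×3 prominence criterion then fires by chance often enough
to matter over 86,400 epochs per day; three-window averaging suppresses this
while keeping 1-s flag granularity. Windows are zero-padded to 512 points so
the frequency grid (~0.49 Hz) is finer than the ±1 Hz harmonic tolerance.

Flagged epochs merge into events: unflagged gaps up to `merge_gap_s`
(default 1 s) are bridged, merged runs shorter than `min_event_s` (default
1 s) are dropped. Detected-versus-truth matching is one-to-one by maximal
overlap, with a match requiring overlap of at least half the ground-truth
event's duration. All thresholds live in `detector_config()`.

## Sleep scoring

Per 5-s epoch, the features are delta power, theta power, the theta/delta
ratio, total (1–48 Hz) power, and EMG RMS. Classification is a fixed-order
cascade with thresholds calibrated from the recording's own feature
percentiles (so scoring is deterministic and gain-invariant):

1. EMG RMS above its 60th percentile → **WAKE** (muscle tone);
2. else delta power above its 60th percentile → **NREM** (slow-wave
   activity);
3. else theta/delta ≥ 1.5 → **REM** (theta-dominant, atonic);
4. else **NREM**.

Percentile thresholds presuppose that the recording actually mixes states:
the wake percentile should approximate the sleep fraction in percent, and 60
matches the roughly 60% sleep a laboratory rat shows over 24 h. Two guards
handle recordings without that structure. If the EMG distribution is
effectively single-cluster (P95/P05 < 2), wake versus sleep is decided for
the whole recording by the ratio of median EMG RMS to the square root of
median EEG total power (≥ 0.25 → wake) — in this montage wake muscle tone is
about half the EEG amplitude, sleep tone well below a tenth. If delta power
is single-cluster (P95/P05 < 3), the NREM percentile rule stands down and
epochs fall through to the theta/delta rule. These guards are what make an
all-wake recording score all wake rather than being split by an arbitrary
percentile.

Smoothing runs to a fixed point (hence idempotent): interior bouts shorter
than 2 epochs are absorbed into the longer flanking bout (ties to the
preceding state; the first and last bouts are boundary-truncated and never
absorbed), and a REM epoch directly following wake is relabelled NREM —
rodents enter REM only from NREM, the same assumption the generator makes.
These two uses of the assumption are deliberately documented together so
that scorer validation against generated data is not mistaken for an
independent test of it.

Validation against a reference hypnogram excludes epochs labelled SWD or
UNSCORED in either sequence, then reports the REM/NREM/WAKE confusion
matrix, per-state agreement (diagonal over reference row total), global
agreement, and Cohen's kappa.

## Analytics conventions

SWD masking happens *after* scoring and *before* state totals: every epoch
overlapping an event is relabelled SWD, so seizure time is excluded from the
state minutes (wake included — discharges happen mostly in wake and would
otherwise inflate it). Onset-state assignment, by contrast, uses the
pre-mask hypnogram, preserving the onset-state percentages. Masking is
state-agnostic: an SWD starting in NREM is excluded from NREM minutes by the
same rule.

A "wake→NREM transition SWD" is an event whose onset state is NREM, whose
enclosing NREM bout begins within 30 s of the end of a WAKE bout, and whose
onset falls within 30 s of that bout start. The 30-s window (six scoring
epochs) is a named configuration constant; the animal-level Fisher
contingency comparison takes observed counts as input and does not depend on
the window.

Events are binned by the clock hour containing their onset (half-open bins;
an onset exactly on a boundary belongs to the later hour), and an event
spanning an hour boundary counts once, in its onset bin. The light/dark
split partitions the 24 h into two 12-h windows at the lights-off clock
time. Means of empty sets are reported as missing (`NA`/JSON `null`), never
as 0, and the percent-of-baseline normalisation refuses a zero baseline.

## Self-contained statistics

The pipeline implements only the tests it needs end-to-end; heavier
modelling (mixed models, factorial ANOVA) is left to external software via
the exported per-animal tables.

* `fisher_exact_2x2`: exact two-sided p by hypergeometric enumeration with
  the minimum-likelihood convention (sum of the probabilities of all tables
  with the observed margins no more probable than the observed one).
* `cohens_kappa`: `(p_o − p_e) / (1 − p_e)`; chance agreement of 1 yields a
  missing value, not an error.
* `pearson_r`: sample correlation with `t = r·√(n−2)/√(1−r²)` and a
  two-sided t-distribution p.
* `two_sample_test`: Welch t (via `stats::t.test`) or Wilcoxon rank sum with
  midranks; for combined n ≤ 20 the rank-sum p is exact — the permutation
  mass of rank sums at least as far from their mean as observed, computed by
  dynamic programming over doubled midranks — otherwise a tie-corrected
  normal approximation with continuity correction.

In group comparisons of cohort tables, near-normal metrics (state minutes)
use Welch t; skewed count metrics (SWD counts) use the rank-sum test, the
same choice the field makes for non-normal per-metric comparisons.

## The synthetic generator: what it emulates, and what it does not

State dynamics are an epoch-stepped Markov chain (one transition per 5-s
epoch), the simplest mechanism that reproduces polyphasic rodent sleep;
dwell times are geometric with means of 2 min (wake), 2 min (NREM) and 1 min
(REM) under the default matrix. The light-phase stationary distribution is
about 34% wake / 53% NREM / 13% REM; during lights-off the wake
self-transition is multiplied by 1.75 (row renormalised), lengthening wake
bouts so that the 24-h sleep fraction lands near the textbook 60% for rats.
WAKE→REM transitions are structurally zero.

Per state, EEG is 1/f-shaped Gaussian noise plus a Gaussian band boost —
NREM: slope 2 with a delta boost at 2.5 Hz, RMS 110 µV (high-amplitude slow
activity); REM: slope 0.8 with a theta boost at 7 Hz strong enough that
theta exceeds delta in every epoch, RMS 55 µV; wake: slope 1, no boost, RMS
60 µV. EMG is white noise at 30/10/3 µV RMS (wake/NREM/REM — atonia), with
8% lognormal epoch-to-epoch level jitter on both channels. Epochs are joined
by 0.25-s equal-power crossfades so state changes do not inject spectral
splatter. The spike-wave template is an asymmetric narrow Gaussian spike
plus a slow negative half-wave repeated at f0 (default 7.5 Hz), scaled to 5×
the local background RMS with 0.1-s cosine ramps; event count is Poisson at
2.5 events/h unless an exact count is requested (`swd_n_events`), durations
are normal (mean 4 s, sd 1.5 s, floor 1.5 s), onsets fall in epochs of the
preferred state (94.8/4.4/0.5% wake/NREM/REM, normalised), and events keep a
5-s minimum separation. Placement failure after bounded retries is an
explicit error, not silent truncation.

Determinism: every generator operation derives its own RNG stream from the
configuration seed by fixed integer mixing, and per-animal cohort seeds
derive from the master seed plus group label and index — enlarging one group
never reshuffles another animal's data.

The generator does **not** emulate microarousals, spindles or K-complexes,
circadian hormone modulation beyond the binary light/dark bias, electrode or
movement artifacts, inter-animal spectral variability, or the strain-specific
wake rhythms that can mimic discharges. Consequently, passing the synthetic
recovery tests shows the pipeline is internally correct — the detector finds
exactly the harmonic structure the template provably contains and the scorer
recovers the signatures the generator planted — but it does not certify
performance on real rat EEG, where the published algorithm class was
validated against human visual scoring at around 90% agreement. The
synthetic acceptance surface (scorer agreement ≥ 90%, kappa ≥ 0.8; detector
recall and precision ≥ 0.9 with ≤ 1 false event per background day) is the
property-based analogue of those figures at the same metric scale, not a
reproduction of them.

## Problem sizes and run times

The packaged checks use the scales the pipeline is designed around: one 24-h
recording (17,280 five-second epochs; 86,400 detection epochs) for scorer
recovery and the detector's false-positive run; a 2-h recording with 40
injected 7-Hz events for recall/precision; 1,000 ground-truth events for the
onset-state distribution; and 100-replicate cohort simulations (9 vs 15
animals, 6-h ground-truth recordings at hypnogram level — signal synthesis
adds nothing to a comparison of REM minutes and event counts) for power and
false-positive calibration. The full suite runs in a few minutes on one
core; peak memory is below 2 GB.

## Known limitations

* The detection epoch grid is 1 s, so event boundaries carry ±1 s
  quantisation; very short discharges (< 1 s) are dropped by design.
* Percentile calibration assumes each recording contains a representative
  state mixture; recordings missing exactly one sleep state (e.g. REM-only
  deprivation days) degrade the NREM/REM split, though the unimodality
  guards handle fully single-state recordings.
* The exact rank-sum DP is quadratic in total rank mass and is used only up
  to combined n = 20, matching its enumeration oracle.
* EDF output quantises to 16 bits over each channel's observed range;
  round-trip error is bounded by one quantisation step and asserted in the
  tests.
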