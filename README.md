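# swdsleep

Analysis of 24-h rodent EEG/EMG recordings in absence-epilepsy models:
automated detection of spike-and-wave discharges (SWDs), automated
wake/NREM/REM sleep scoring, and the downstream state, bout, transition and
correlation analytics that turn a day of polygraphy into per-animal summary
tables and group statistics. A synthetic EEG/EMG generator with known ground
truth makes every stage of the pipeline testable without animal data.

It is written for electrophysiologists working with chronically implanted
rats or mice (skull-surface EEG plus nuchal EMG, sampling rates around
250 Hz) who need reproducible seizure and sleep quantification over
light–dark cycles.

## What it computes

**SWD detection.** An absence seizure's EEG correlate is a run of periodic
high-amplitude spike-and-wave complexes with a fundamental frequency
f0 ∈ [5, 10] Hz. Because each complex is a sharp spike riding on a slow wave,
its Fourier series puts power at f0 *and its harmonics* — the detector flags a
1-s epoch when the Welch spectrum has a prominent local maximum at f0 in the
5–10 Hz band (peak ≥ 3 × a running-median spectral baseline, and the global
spectral maximum), a second local maximum at 2·f0 ± 1 Hz, and an epoch RMS at
least twice the recording's median epoch RMS. Flagged epochs are merged into
events (gaps ≤ 1 s bridged, events < 1 s dropped).

**Sleep scoring.** A transparent percentile-threshold cascade on per-epoch
(5 s) features, auto-calibrated per recording so it is invariant to headstage
gain: high EMG RMS → wake; else high delta (1–5 Hz) power → NREM; else
theta/delta ratio ≥ 1.5 → REM; else NREM. Bouts shorter than 2 epochs are
smoothed away and wake→REM transitions are forbidden (rodent physiology).
Agreement against a reference hypnogram is reported as a 3×3 confusion
matrix, per-state and global agreement, and Cohen's kappa.

**Analytics.** Bout segmentation; state minute totals with SWD epochs masked
out (seizure time is not wake time); hourly and 12:12 light–dark aggregation
anchored to clock time; SWD onset-state percentages; flagging of SWDs that
initiate at wake→NREM transitions; percent-of-baseline drug-window
normalisation; and self-contained statistics — exact two-sided Fisher test
(minimum-likelihood convention), Cohen's kappa, Pearson correlation with
t/df/p, Welch t and exact/midrank Wilcoxon rank-sum tests.

**Synthetic data.** An epoch-stepped Markov chain over (wake, NREM, REM) with
a lights-off wake bias generates ground-truth hypnograms; state-conditioned
1/f EEG spectra (NREM delta boost, REM theta boost) and state-dependent EMG
tone generate signals; spike-wave trains with controllable rate, duration,
fundamental and amplitude gain are injected at state-preferred onsets
(defaults: 94.8% wake / 4.4% NREM / 0.5% REM). Cohorts with group-level
effect multipliers (REM dwell, SWD rate) support power studies.

## Worked example

```r
library(swdsleep)

# simulate 6 h with 30 injected spike-wave events and known ground truth
cfg <- sim_config(duration_s = 21600, swd_n_events = 30, seed = 42)
sim <- simulate_recording(cfg)

# detect SWDs and summarise them
events <- detect_swds(sim$recording)
event_summary(events)
#> $count           [1] 30
#> $mean_duration_s [1] 4.293131
#> $total_duration_s [1] 128.7939

# score sleep and validate against the ground-truth hypnogram
hyp <- score_sleep(sim$recording)
v <- validate_against(hyp, sim$hypnogram)
round(v$global_agreement_pct, 1)  #> 94.6
round(v$kappa, 3)                 #> 0.908

# detection performance against the injected ground truth
m <- match_events(sim$events, events)
c(m$recall, m$precision)          #> 1 1

# per-animal summary with SWD masking and clock-anchored aggregation
animal_summary(hyp, events)
#> AnimalSummary: 30 SWDs (total 128.8 s), 360 min recorded
#>   minutes: WAKE 120.2, NREM 183.5, REM 51.7

# the published animal-level transition table: 15/15 vs 3/9 animals
fisher_exact_2x2(matrix(c(15, 3, 0, 6), 2))
#> [1] 0.0006240899
```

The detector found every injected event with no false positives; the scorer
recovered the hypnogram at 94.6% epoch agreement (kappa 0.91) on this 6-h
recording — on the 24-h recordings the pipeline is designed for, agreement is
higher because the percentile calibration sees the full sleep–wake cycle.

A command-line wrapper ships in `inst/scripts/swdtool.R`
(`simulate`, `detect-swd`, `score-sleep`, `validate`, `analyze`) for running
the same steps on EDF/CSV files from a shell.

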