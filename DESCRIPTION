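Package: swdsleep
Title: Spike-Wave Discharge Detection and Automated Sleep Scoring for Rodent EEG/EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 24-h rodent electroencephalography (EEG) and electromyography
    (EMG) analysis in absence-epilepsy models: detection of spike-and-wave
    discharges (SWDs) by harmonic spectral peaks with a 5-10 Hz fundamental,
    percentile-calibrated automated sleep scoring (wake/NREM/REM), Welch band-power
    spectral analysis, hypnogram bout and transition analytics with light-dark
    aggregation, and the self-contained statistics (Fisher exact, Cohen's kappa,
    Pearson correlation, Welch t and exact rank-sum tests) used to compare groups.
    Includes a synthetic EEG/EMG generator with known ground truth (Markov state
    dynamics, state-conditioned spectra, injectable spike-wave events) so the whole
    pipeline is testable without animal recordings, plus EDF and CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
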