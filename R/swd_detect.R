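#' SWD detector configuration
#'
#' The detector flags 1-s epochs whose spectrum shows a prominent fundamental
#' peak in the 5-10 Hz band together with its first harmonic, and whose
#' amplitude exceeds a recording-relative threshold; flagged epochs are merged
#' into events.
#'
#' @param fundamental_lo_hz,fundamental_hi_hz fundamental search band
#'   (defaults 5 and 10 Hz).
#' @param harmonic_tolerance_hz allowed deviation of the harmonic peak from
#'   `2 * f0` (default 1 Hz).
#' @param peak_prominence_ratio fundamental peak must exceed this multiple of
#'   the median-smoothed local spectral baseline (default 3).
#' @param harmonic_min_ratio minimum baseline ratio for the harmonic peak
#'   (default 2).
#' @param amplitude_gain_threshold epoch RMS must exceed this multiple of the
#'   recording's median epoch RMS (default 2; relative, so detection is
#'   invariant to overall signal scaling).
#' @param require_dominant require the fundamental to be the global PSD
#'   maximum over `[1, 48]` Hz (default `TRUE`): during an SWD the fundamental
#'   dominates the whole spectrum, and this rejects incidental noise peaks in
#'   delta-dominant sleep epochs.
#' @param min_event_s discard merged events shorter than this (default 1 s).
#' @param merge_gap_s bridge unflagged gaps up to this long between flagged
#'   runs (default 1 s, i.e. one detection epoch).
#' @param detection_epoch_s detection epoch length (default 1 s; finer than
#'   the 5-s scoring epoch so event boundaries resolve to about a second).
#' @param baseline_halfwidth_hz half-width of the running-median spectral
#'   baseline (default 2 Hz; robust to the 1/f slope).
#' @return a list of class `"DetectorConfig"`.
#' @export
detector_config <- function(fundamental_lo_hz = 5, fundamental_hi_hz = 10,
                            harmonic_tolerance_hz = 1.0,
                            peak_prominence_ratio = 3,
                            harmonic_min_ratio = 2,
                            amplitude_gain_threshold = 2,
                            require_dominant = TRUE,
                            min_event_s = 1.0, merge_gap_s = 1.0,
                            detection_epoch_s = 1.0,
                            baseline_halfwidth_hz = 2) {
  cfg <- structure(as.list(environment()), class = "DetectorConfig")
  if (!(cfg$fundamental_lo_hz > 0 &&
        cfg$fundamental_lo_hz < cfg$fundamental_hi_hz))
    stop("need 0 < fundamental_lo_hz < fundamental_hi_hz")
  for (f in c("harmonic_tolerance_hz", "peak_prominence_ratio",
              "harmonic_min_ratio", "amplitude_gain_threshold",
              "min_event_s", "detection_epoch_s"))
    if (cfg[[f]] <= 0) stop(f, " must be > 0")
  if (cfg$merge_gap_s < 0) stop("merge_gap_s must be >= 0")
  cfg
}

# running-median spectral baseline
psd_baseline <- function(power, df, halfwidth_hz) {
  k <- 2 * floor(halfwidth_hz / df) + 1
  k <- min(k, 2 * floor((length(power) - 1) / 2) + 1)
  if (k < 3) return(power)
  stats::runmed(power, k, endrule = "median")
}

#' Score one detection epoch for SWD content
#'
#' The epoch is flagged iff (i) there is a local PSD maximum `f0` inside the
#' fundamental band whose ratio to the median-smoothed baseline reaches
#' `peak_prominence_ratio` (and, with `require_dominant`, that bin is the
#' global PSD maximum over 1-48 Hz), (ii) a local maximum lies within
#' `harmonic_tolerance_hz` of `2 * f0` with baseline ratio at least
#' `harmonic_min_ratio`, and (iii) `epoch_rms >= amplitude_gain_threshold *
#' rms_reference`.
#'
#' @param psd a `"PsdEstimate"` for the epoch (resolution must not exceed
#'   `harmonic_tolerance_hz`).
#' @param epoch_rms RMS amplitude of the epoch (uV).
#' @param cfg a `"DetectorConfig"`.
#' @param rms_reference the recording's median epoch RMS (uV).
#' @return `list(flag = logical, f0 = Hz or NA)`.
#' @export
epoch_swd_score <- function(psd, epoch_rms, cfg = detector_config(),
                            rms_reference = 1) {
  freqs <- psd$freqs; power <- psd$power
  df <- freqs[2] - freqs[1]
  if (df > cfg$harmonic_tolerance_hz * 1.05)
    stop("PSD resolution (", signif(df, 3), " Hz) exceeds harmonic tolerance")
  if (epoch_rms < cfg$amplitude_gain_threshold * rms_reference)
    return(list(flag = FALSE, f0 = NA_real_))
  base <- psd_baseline(power, df, cfg$baseline_halfwidth_hz)
  ratio <- power / pmax(base, .Machine$double.eps)
  n <- length(power)
  locmax <- c(FALSE, power[2:(n - 1)] > power[1:(n - 2)] &
                power[2:(n - 1)] >= power[3:n], FALSE)
  in_band <- freqs >= cfg$fundamental_lo_hz & freqs <= cfg$fundamental_hi_hz
  cand <- which(locmax & in_band & ratio >= cfg$peak_prominence_ratio)
  if (!length(cand)) return(list(flag = FALSE, f0 = NA_real_))
  i0 <- cand[which.max(power[cand])]
  if (cfg$require_dominant) {
    dom <- freqs >= 1 & freqs <= 48
    if (power[i0] < max(power[dom])) return(list(flag = FALSE, f0 = NA_real_))
  }
  f0 <- freqs[i0]
  near <- which(locmax & abs(freqs - 2 * f0) <= cfg$harmonic_tolerance_hz &
                  ratio >= cfg$harmonic_min_ratio)
  if (!length(near)) return(list(flag = FALSE, f0 = NA_real_))
  list(flag = TRUE, f0 = f0)
}

#' Merge per-epoch SWD flags into events
#'
#' Consecutive flagged detection epochs become one event; unflagged gaps no
#' longer than `merge_gap_s` between flagged runs are bridged; merged events
#' shorter than `min_event_s` are discarded.
#'
#' @param flags logical vector, one per detection epoch.
#' @param cfg a `"DetectorConfig"`.
#' @param epoch_len_s detection epoch length (default from `cfg`).
#' @return an `EventTable` (onset states unassigned).
#' @export
merge_flags_to_events <- function(flags, cfg = detector_config(),
                                  epoch_len_s = cfg$detection_epoch_s) {
  flags <- as.logical(flags)
  if (!length(flags) || !any(flags)) return(event_table())
  r <- rle(flags)
  # bridge interior gaps of unflagged epochs <= merge_gap_s
  if (length(r$values) > 2) {
    interior <- seq(2, length(r$values) - 1)
    bridge <- interior[!r$values[interior] &
                         r$lengths[interior] * epoch_len_s <= cfg$merge_gap_s]
    r$values[bridge] <- TRUE
    flags <- inverse.rle(r)
    r <- rle(flags)
  }
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths
  keep <- r$values
  s <- starts_idx[keep] * epoch_len_s
  e <- ends_idx[keep] * epoch_len_s
  dur_ok <- (e - s) >= cfg$min_event_s - 1e-9
  event_table(s[dur_ok], e[dur_ok])
}

# Welch PSDs on the detection grid: each 1-s epoch's PSD averages the 1-s Hann
# windows (50% overlap) whose start lies within half a window of the epoch,
# i.e. windows starting at t-0.5, t, t+0.5 s. Averaging three windows tames
# the chi-squared(2) noise of a single periodogram while keeping ~1-Hz
# resolution and 1-s flag granularity; windows are zero-padded to the next
# power of two so the frequency grid is finer than the harmonic tolerance.
detection_psds <- function(x, fs, epoch_len_s, block = 2048L) {
  nwin <- round(epoch_len_s * fs)
  hop <- floor(nwin / 2)
  nep <- floor(length(x) / nwin)
  if (nep < 1) return(NULL)
  x <- x - mean(x)
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- hann(nwin)
  nfft <- 2^ceiling(log2(2 * nwin))
  nfreq <- floor(nfft / 2) + 1
  pw <- matrix(0, nfreq, nep)
  freqs <- NULL
  # window j covers samples [starts[j], starts[j]+nwin); epoch k (1-based)
  # uses windows starting in [(k-1)*nwin - hop, (k-1)*nwin + hop];
  # processed in blocks of epochs to bound the FFT working set
  for (k0 in seq(1L, nep, by = block)) {
    k1 <- min(nep, k0 + block - 1L)
    jset <- which(starts >= (k0 - 1) * nwin - hop + 1 &
                    starts <= (k1 - 1) * nwin + hop + 1)
    idx <- outer(0:(nwin - 1L), starts[jset], `+`)
    pc <- psd_columns(matrix(x[idx], nrow = nwin), fs, w, nfft)
    freqs <- pc$freqs
    for (k in k0:k1) {
      j <- which(starts[jset] >= (k - 1) * nwin - hop + 1 &
                   starts[jset] <= (k - 1) * nwin + hop + 1)
      pw[, k] <- rowMeans(pc$power[, j, drop = FALSE])
    }
  }
  list(freqs = freqs, power = pw, nep = nep, nwin = nwin)
}

#' Detect spike-wave discharges in a recording
#'
#' Runs [epoch_swd_score()] on every detection epoch of the configured EEG
#' channel and merges the flags with [merge_flags_to_events()].
#'
#' @param rec a `Recording` with at least one EEG channel.
#' @param cfg a `"DetectorConfig"`.
#' @param channel channel name (default: first EEG channel).
#' @return an `EventTable` (onset states unassigned; see
#'   [assign_event_states()]).
#' @export
detect_swds <- function(rec, cfg = detector_config(), channel = NULL) {
  x <- get_channel(rec, channel, role = "EEG")
  if (!length(x)) return(event_table())
  dp <- detection_psds(x, rec$fs, cfg$detection_epoch_s)
  if (is.null(dp)) return(event_table())
  spe <- dp$nwin
  em <- matrix(x[seq_len(dp$nep * spe)], nrow = spe)
  ep_rms <- sqrt(colMeans(em^2))
  ref <- stats::median(ep_rms)
  df <- dp$freqs[2] - dp$freqs[1]
  flags <- logical(dp$nep)
  for (k in seq_len(dp$nep)) {
    sc <- epoch_swd_score(new_psd(dp$freqs, dp$power[, k], 3,
                                  cfg$detection_epoch_s),
                          ep_rms[k], cfg, ref)
    flags[k] <- sc$flag
  }
  merge_flags_to_events(flags, cfg, dp$nwin / rec$fs)
}

#' Count, mean and total duration of events
#'
#' @param ev an `EventTable`.
#' @return `list(count, mean_duration_s, total_duration_s)`; the mean of an
#'   empty table is `NA` (missing), never 0.
#' @export
event_summary <- function(ev) {
  validate_events(ev)
  n <- nrow(ev)
  tot <- sum(ev$duration_s)
  list(count = n,
       mean_duration_s = if (n > 0) tot / n else NA_real_,
       total_duration_s = tot)
}

#' Match detected events against ground truth
#'
#' A detection matches a ground-truth event when their overlap covers at least
#' `min_overlap_frac` of the ground-truth duration. Assignment is one-to-one by
#' decreasing overlap (a detection spanning two truths is assigned to the one
#' it overlaps most).
#'
#' @param truth,detected `EventTable`s.
#' @param min_overlap_frac minimum overlap as a fraction of the ground-truth
#'   event duration (default 0.5).
#' @return `list(recall, precision, n_truth, n_detected, matched)` where
#'   `matched` is the number of matched pairs.
#' @export
match_events <- function(truth, detected, min_overlap_frac = 0.5) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0 || nd == 0) {
    return(list(recall = if (nt == 0) NA_real_ else 0,
                precision = if (nd == 0) NA_real_ else 0,
                n_truth = nt, n_detected = nd, matched = 0L))
  }
  ov <- matrix(0, nt, nd)
  for (i in seq_len(nt)) {
    o <- pmin(truth$end_s[i], detected$end_s) -
      pmax(truth$start_s[i], detected$start_s)
    ov[i, ] <- pmax(o, 0)
  }
  ok <- ov >= min_overlap_frac * truth$duration_s
  ov[!ok] <- 0
  matched <- 0L
  used_t <- logical(nt); used_d <- logical(nd)
  repeat {
    m <- which.max(ov)
    if (ov[m] <= 0) break
    i <- (m - 1) %% nt + 1; j <- (m - 1) %/% nt + 1
    matched <- matched + 1L
    used_t[i] <- TRUE; used_d[j] <- TRUE
    ov[i, ] <- 0; ov[, j] <- 0
  }
  list(recall = matched / nt, precision = matched / nd,
       n_truth = nt, n_detected = nd, matched = matched)
}
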