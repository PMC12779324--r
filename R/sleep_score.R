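#' Sleep-scorer configuration
#'
#' A transparent percentile-threshold cascade: epochs with EMG tone above a
#' per-recording percentile are wake; of the rest, epochs with delta power
#' above a per-recording percentile are NREM; of the rest, epochs with a
#' theta/delta ratio at or above a fixed threshold are REM; anything else is
#' NREM. Percentile calibration per recording makes the scorer invariant to
#' headstage gain.
#'
#' @param emg_wake_percentile percentile of epoch EMG RMS above which an epoch
#'   is wake (default 60; should approximate the recording's sleep fraction in
#'   percent).
#' @param delta_nrem_percentile percentile of epoch delta power above which a
#'   non-wake epoch is NREM (default 60).
#' @param theta_delta_rem_threshold theta/delta power ratio at or above which
#'   a remaining epoch is REM (default 1.5).
#' @param smoothing_min_bout_epochs bouts shorter than this are absorbed into
#'   the flanking state (default 2).
#' @param forbid_wake_to_rem relabel REM epochs that directly follow wake as
#'   NREM (default `TRUE`; rodents do not enter REM from wake).
#' @param emg_unimodal_spread,delta_unimodal_spread guards for recordings
#'   without distinct feature clusters: percentile thresholds only separate
#'   states when the feature distribution actually spreads. If the EMG P95/P05
#'   ratio falls below `emg_unimodal_spread` (default 2) the recording is
#'   treated as single-tone and wake/sleep is decided for all epochs at once
#'   by the EMG-to-EEG amplitude ratio (`emg_eeg_wake_ratio`); if the delta
#'   P95/P05 ratio falls below `delta_unimodal_spread` (default 3) the NREM
#'   percentile rule defers to the theta/delta rule.
#' @param emg_eeg_wake_ratio median EMG RMS over root median EEG total power
#'   at or above which a single-tone recording counts as wake (default 0.25;
#'   wake muscle tone is about half the EEG amplitude in the rodent montage,
#'   sleep tone well below a tenth).
#' @return a list of class `"ScorerConfig"`.
#' @export
scorer_config <- function(emg_wake_percentile = 60,
                          delta_nrem_percentile = 60,
                          theta_delta_rem_threshold = 1.5,
                          smoothing_min_bout_epochs = 2,
                          forbid_wake_to_rem = TRUE,
                          emg_unimodal_spread = 2,
                          delta_unimodal_spread = 3,
                          emg_eeg_wake_ratio = 0.25) {
  cfg <- structure(as.list(environment()), class = "ScorerConfig")
  for (f in c("emg_wake_percentile", "delta_nrem_percentile"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 100)
      stop(f, " must lie in (0, 100)")
  if (cfg$theta_delta_rem_threshold <= 0)
    stop("theta_delta_rem_threshold must be > 0")
  if (cfg$smoothing_min_bout_epochs < 1)
    stop("smoothing_min_bout_epochs must be >= 1")
  cfg
}

#' Per-epoch scoring features
#'
#' Delta and theta band power and total power of the EEG (Welch, per epoch),
#' theta/delta ratio, and EMG RMS. Epochs with non-positive delta or vanishing
#' total power are flagged degenerate (scored UNSCORED downstream).
#'
#' @param rec a `Recording` with EEG and EMG channels.
#' @param channel_eeg,channel_emg channel names (defaults: first of each role).
#' @param epoch_len_s scoring epoch length, seconds (default 5).
#' @param scheme a `"BandScheme"` providing the delta and theta bands.
#' @return data.frame of class `"EpochFeatures"` with columns `delta_power`,
#'   `theta_power`, `total_power`, `theta_delta_ratio`, `emg_rms`,
#'   `degenerate`.
#' @export
extract_features <- function(rec, channel_eeg = NULL, channel_emg = NULL,
                             epoch_len_s = 5, scheme = band_scheme()) {
  eeg <- get_channel(rec, channel_eeg, role = "EEG")
  emg <- get_channel(rec, channel_emg, role = "EMG")
  ep <- epoch_psds(eeg, rec$fs, epoch_len_s)
  bp <- apply_bands(ep$freqs, ep$power, scheme)
  total <- band_integral_cols(ep$freqs, ep$power, scheme$lo_hz[1],
                              scheme$hi_hz[nrow(scheme)])
  emg_ep <- epoch_matrix(emg, rec$fs, epoch_len_s)
  nep <- ncol(bp)
  emg_rms <- sqrt(colMeans(emg_ep^2))[seq_len(nep)]
  delta <- bp["delta", ]; theta <- bp["theta", ]
  degen <- !(delta > 0) | total <= .Machine$double.eps
  ratio <- ifelse(degen, NA_real_, theta / delta)
  out <- data.frame(delta_power = delta, theta_power = theta,
                    total_power = total, theta_delta_ratio = ratio,
                    emg_rms = emg_rms, degenerate = degen)
  class(out) <- c("EpochFeatures", "data.frame")
  out
}

#' Classify epochs from features (raw labels, no smoothing)
#'
#' Rule cascade with thresholds auto-calibrated from the recording's own
#' feature percentiles; see [scorer_config()].
#'
#' @param features an `"EpochFeatures"` data.frame.
#' @param cfg a `"ScorerConfig"`.
#' @return character vector of raw labels (`WAKE`/`NREM`/`REM`/`UNSCORED`).
#' @export
classify_epochs <- function(features, cfg = scorer_config()) {
  if (!nrow(features)) stop("no epochs to classify")
  ok <- !features$degenerate
  if (!any(ok)) stop("all epochs are degenerate; cannot calibrate thresholds")
  eps <- .Machine$double.eps
  lab <- rep("UNSCORED", nrow(features))
  emg <- features$emg_rms[ok]
  q <- stats::quantile(emg, c(0.05, 0.95), names = FALSE)
  if (q[2] / max(q[1], eps) < cfg$emg_unimodal_spread) {
    # single muscle-tone cluster: wake/sleep decided for the whole recording
    rel <- stats::median(emg) /
      sqrt(max(stats::median(features$total_power[ok]), eps))
    if (rel >= cfg$emg_eeg_wake_ratio) {
      lab[ok] <- "WAKE"
      return(lab)
    }
  } else {
    emg_thr <- stats::quantile(emg, cfg$emg_wake_percentile / 100,
                               names = FALSE)
    lab[ok & features$emg_rms > emg_thr] <- "WAKE"
  }
  delta <- features$delta_power[ok]
  qd <- stats::quantile(delta, c(0.05, 0.95), names = FALSE)
  if (qd[2] / max(qd[1], eps) >= cfg$delta_unimodal_spread) {
    delta_thr <- stats::quantile(delta, cfg$delta_nrem_percentile / 100,
                                 names = FALSE)
    rest <- ok & lab == "UNSCORED"
    lab[rest & features$delta_power > delta_thr] <- "NREM"
  }
  rest <- ok & lab == "UNSCORED"
  lab[rest & features$theta_delta_ratio >= cfg$theta_delta_rem_threshold] <- "REM"
  lab[ok & lab == "UNSCORED"] <- "NREM"
  lab
}

#' Smooth a raw label sequence into a hypnogram
#'
#' Repeatedly (to a fixed point, hence idempotent): (i) interior bouts shorter
#' than `smoothing_min_bout_epochs` are absorbed into the longer flanking bout
#' (ties go to the preceding state; the first and last bouts are truncated by
#' the recording boundaries and are never absorbed); (ii) with
#' `forbid_wake_to_rem`, a REM
#' epoch whose (updated) predecessor is WAKE is relabeled NREM. UNSCORED
#' epochs are left untouched and never absorb neighbours.
#'
#' @param labels character vector of raw labels.
#' @param cfg a `"ScorerConfig"`.
#' @param epoch_len_s epoch length for the returned hypnogram (default 5).
#' @return a `Hypnogram`.
#' @export
smooth_hypnogram <- function(labels, cfg = scorer_config(), epoch_len_s = 5) {
  lab <- as.character(labels)
  for (pass in seq_len(50)) {
    new <- absorb_short_bouts(lab, cfg$smoothing_min_bout_epochs)
    if (cfg$forbid_wake_to_rem) new <- relabel_wake_rem(new)
    if (identical(new, lab)) break
    lab <- new
  }
  hypnogram(lab, epoch_len_s)
}

# interior bouts only: the first and last bouts are truncated by the
# recording boundaries, so their true length is unknown and they are never
# absorbed
absorb_short_bouts <- function(lab, min_epochs) {
  r <- rle(lab)
  if (length(r$values) < 3) return(lab)
  repeat {
    short <- which(r$lengths < min_epochs & r$values != "UNSCORED")
    short <- setdiff(short, c(1L, length(r$values)))
    short <- short[vapply(short, function(i) {
      (i > 1 && r$values[i - 1] != "UNSCORED") ||
        (i < length(r$values) && r$values[i + 1] != "UNSCORED")
    }, TRUE)]
    if (!length(short)) break
    i <- short[1]
    prev_len <- if (i > 1 && r$values[i - 1] != "UNSCORED") r$lengths[i - 1] else -1
    next_len <- if (i < length(r$values) && r$values[i + 1] != "UNSCORED")
      r$lengths[i + 1] else -1
    take_prev <- prev_len >= next_len   # tie -> preceding state
    r$values[i] <- if (take_prev) r$values[i - 1] else r$values[i + 1]
    # merge equal neighbours
    r <- rle(inverse.rle(r))
    if (length(r$values) < 2) break
  }
  inverse.rle(r)
}

relabel_wake_rem <- function(lab) {
  if (length(lab) < 2) return(lab)
  for (i in 2:length(lab)) {
    if (lab[i] == "REM" && lab[i - 1] == "WAKE") lab[i] <- "NREM"
  }
  lab
}

#' Score sleep for a whole recording
#'
#' Full pipeline: [extract_features()], [classify_epochs()],
#' [smooth_hypnogram()], on the 5-s scoring grid.
#'
#' @param rec a `Recording` with EEG and EMG channels.
#' @param cfg a `"ScorerConfig"`.
#' @param channel_eeg,channel_emg channel names (defaults: first of each role).
#' @param epoch_len_s scoring epoch length (default 5 s).
#' @param scheme a `"BandScheme"`.
#' @return a `Hypnogram`.
#' @export
score_sleep <- function(rec, cfg = scorer_config(), channel_eeg = NULL,
                        channel_emg = NULL, epoch_len_s = 5,
                        scheme = band_scheme()) {
  feats <- extract_features(rec, channel_eeg, channel_emg, epoch_len_s, scheme)
  raw <- classify_epochs(feats, cfg)
  smooth_hypnogram(raw, cfg, epoch_len_s)
}

#' Validate an automated hypnogram against a reference
#'
#' Builds the 3x3 confusion matrix over (REM, NREM, WAKE) with rows = reference
#' and columns = automated labels, and reports per-state agreement (diagonal /
#' reference row total), global agreement (trace / total) and Cohen's kappa.
#' Epochs where either hypnogram is SWD or UNSCORED are excluded from the
#' denominators.
#'
#' @param automated,reference `Hypnogram`s on the same epoch grid.
#' @return `list(confusion, per_state_agreement_pct, global_agreement_pct,
#'   kappa, n_epochs)`.
#' @export
validate_against <- function(automated, reference) {
  if (n_epochs(automated) != n_epochs(reference) ||
      abs(automated$epoch_len_s - reference$epoch_len_s) > 1e-9)
    stop("hypnograms are on different epoch grids")
  keep <- automated$labels %in% SLEEP_STATES &
    reference$labels %in% SLEEP_STATES
  states <- c("REM", "NREM", "WAKE")
  cm <- table(factor(reference$labels[keep], levels = states),
              factor(automated$labels[keep], levels = states))
  cm <- unclass(as.matrix(cm))
  tot <- sum(cm)
  per_state <- ifelse(rowSums(cm) > 0, 100 * diag(cm) / rowSums(cm), NA_real_)
  names(per_state) <- states
  list(confusion = cm,
       per_state_agreement_pct = per_state,
       global_agreement_pct = if (tot > 0) 100 * sum(diag(cm)) / tot else NA_real_,
       kappa = if (tot > 0) cohens_kappa(cm) else NA_real_,
       n_epochs = tot)
}
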