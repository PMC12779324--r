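#' Default per-epoch state-transition matrix
#'
#' Row-stochastic matrix over (WAKE, NREM, REM) applied once per 5-s epoch
#' during the light phase. Mean dwell times are 2 min (wake), 2 min (NREM) and
#' 1 min (REM); the stationary distribution is approximately 34% wake, 53%
#' NREM, 13% REM, so that with the default dark-phase wake bias the 24-h sleep
#' fraction is close to 60%, a textbook figure for laboratory rats.
#' WAKE -> REM is structurally zero (standard rodent physiology).
#'
#' @return 3x3 row-stochastic matrix with dimnames over the three states.
#' @export
default_transition_matrix <- function() {
  P <- rbind(
    WAKE = c(0.958333, 0.041667, 0),
    NREM = c(0.021225, 0.958333, 0.020442),
    REM  = c(0.022442, 0.060892, 0.916666))
  colnames(P) <- SLEEP_STATES
  P / rowSums(P)
}

#' Default state-conditioned spectral/EMG parameters
#'
#' Per state: `slope` (1/f exponent of the EEG background), `boost_hz` /
#' `boost_bw_hz` / `boost_gain` (Gaussian band boost: NREM delta, REM theta),
#' `eeg_rms` and `emg_rms` targets in microvolts, and `rms_jitter_sd` (log-sd
#' of per-epoch lognormal level jitter). Values emulate the canonical rodent
#' signatures: NREM high-amplitude slow (delta-dominant) EEG with moderate
#' muscle tone, REM theta-dominant EEG with atonia, wake broadband EEG with
#' high EMG.
#'
#' @return named list of per-state parameter lists.
#' @export
default_state_spectra <- function() {
  list(
    WAKE = list(slope = 1.0, boost_hz = NA, boost_bw_hz = NA, boost_gain = 0,
                eeg_rms = 60, emg_rms = 30, rms_jitter_sd = 0.08),
    NREM = list(slope = 2.0, boost_hz = 2.5, boost_bw_hz = 1.5, boost_gain = 3,
                eeg_rms = 110, emg_rms = 10, rms_jitter_sd = 0.08),
    REM  = list(slope = 0.8, boost_hz = 7, boost_bw_hz = 2.0, boost_gain = 14,
                eeg_rms = 55, emg_rms = 3, rms_jitter_sd = 0.08))
}

#' Simulation configuration
#'
#' Parameters of the synthetic EEG/EMG generator: recording geometry, Markov
#' state dynamics over a 12:12 light-dark cycle, state-conditioned spectra and
#' EMG tone, and injectable spike-wave events.
#'
#' @param duration_s recording length, seconds (default 24 h).
#' @param epoch_len_s scoring epoch length, seconds (default 5).
#' @param fs sampling rate, Hz (default 250.4).
#' @param state_transition_matrix 3x3 row-stochastic matrix over
#'   (WAKE, NREM, REM), one transition per epoch.
#' @param dark_phase_wake_bias multiplicative factor applied to the wake
#'   self-transition during lights-off, row renormalised (default 1.75; wake
#'   bouts lengthen in the active phase).
#' @param state_spectra per-state parameters, see [default_state_spectra()].
#' @param swd_rate_per_h expected SWD events per hour (default 2.5; event count
#'   is Poisson unless `swd_n_events` is given).
#' @param swd_n_events exact event count override (default `NULL`).
#' @param swd_duration_s `c(mean, sd)` of event duration in seconds
#'   (default 4, 1.5; truncated below at `swd_min_duration_s`).
#' @param swd_min_duration_s minimum event duration (default 1.5 s).
#' @param swd_min_gap_s minimum gap between events (default 5 s).
#' @param swd_f0_hz spike-wave fundamental, within `[5, 10]` (default 7.5).
#' @param swd_amplitude_gain event amplitude as a multiple of the local
#'   background RMS (default 5).
#' @param swd_state_preference probability vector over onset states
#'   (WAKE, NREM, REM); default is the normalised (94.8, 4.4, 0.5)% split.
#' @param start_clock,lights_off_clock clock anchors (`"HH:MM"`); defaults
#'   07:00 start (lights on) and 19:00 lights off.
#' @param seed integer RNG seed; every generator operation derives its own
#'   stream from it via [mix_seed()].
#' @return a validated list of class `"SimConfig"`.
#' @export
sim_config <- function(duration_s = 86400, epoch_len_s = 5, fs = 250.4,
                       state_transition_matrix = default_transition_matrix(),
                       dark_phase_wake_bias = 1.75,
                       state_spectra = default_state_spectra(),
                       swd_rate_per_h = 2.5, swd_n_events = NULL,
                       swd_duration_s = c(mean = 4, sd = 1.5),
                       swd_min_duration_s = 1.5, swd_min_gap_s = 5,
                       swd_f0_hz = 7.5, swd_amplitude_gain = 5,
                       swd_state_preference = c(WAKE = 0.948, NREM = 0.044,
                                                REM = 0.005) / 0.997,
                       start_clock = "07:00", lights_off_clock = "19:00",
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "SimConfig")
  validate_sim_config(cfg)
  cfg
}

#' Validate a SimConfig
#'
#' Enforces: row-stochastic non-negative transition matrix (rows sum to 1
#' within 1e-9), WAKE->REM entry zero, `swd_f0_hz` within `[5, 10]`, sampling
#' rate above twice the highest default band edge, and a state-preference
#' vector summing to 1 within 1e-9.
#'
#' @param cfg a `"SimConfig"`.
#' @return `cfg`, invisibly.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  P <- cfg$state_transition_matrix
  if (!is.matrix(P) || any(dim(P) != 3) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9))
    stop("configuration error: state_transition_matrix must be 3x3, ",
         "non-negative, rows summing to 1 within 1e-9")
  if (P[1, 3] != 0)
    stop("configuration error: WAKE -> REM transition must be 0")
  if (cfg$swd_f0_hz < 5 || cfg$swd_f0_hz > 10)
    stop("configuration error: swd_f0_hz must lie in [5, 10]")
  if (cfg$fs <= 2 * 48)
    stop("configuration error: fs must exceed twice the highest band edge")
  if (abs(sum(cfg$swd_state_preference) - 1) > 1e-9)
    stop("configuration error: swd_state_preference must sum to 1")
  if (any(cfg$swd_state_preference < 0))
    stop("configuration error: swd_state_preference must be non-negative")
  if (cfg$duration_s < 0) stop("duration_s must be >= 0")
  if (cfg$epoch_len_s <= 0) stop("epoch_len_s must be > 0")
  if (cfg$dark_phase_wake_bias <= 0) stop("dark_phase_wake_bias must be > 0")
  invisible(cfg)
}

# transition matrix with the dark-phase wake bias applied
bias_matrix <- function(P, bias) {
  P[1, 1] <- P[1, 1] * bias
  P[1, ] <- P[1, ] / sum(P[1, ])
  P
}

#' Generate a ground-truth hypnogram
#'
#' Epoch-stepped Markov chain over (WAKE, NREM, REM); during lights-off the
#' wake self-transition is multiplied by `dark_phase_wake_bias` (row
#' renormalised). The chain starts in WAKE. Deterministic given `cfg$seed`.
#'
#' @param cfg a `"SimConfig"`.
#' @param init_state initial state (default `"WAKE"`).
#' @return a `Hypnogram`.
#' @export
generate_hypnogram <- function(cfg, init_state = "WAKE") {
  validate_sim_config(cfg)
  nep <- floor(cfg$duration_s / cfg$epoch_len_s)
  if (nep == 0) return(hypnogram(character(), cfg$epoch_len_s))
  set.seed(mix_seed(cfg$seed, "hypnogram"))
  Plight <- cfg$state_transition_matrix
  Pdark <- bias_matrix(Plight, cfg$dark_phase_wake_bias)
  cl <- cumsum_rows(Plight); cd <- cumsum_rows(Pdark)
  start_h <- parse_clock(cfg$start_clock)
  hod <- (start_h + (seq_len(nep) - 1) * cfg$epoch_len_s / 3600) %% 24
  dark <- is_dark_phase(hod, cfg$lights_off_clock)
  u <- stats::runif(nep)
  s <- integer(nep)
  s[1] <- match(init_state, SLEEP_STATES)
  for (k in seq_len(nep - 1L)) {
    cm <- if (dark[k]) cd else cl
    row <- cm[s[k], ]
    s[k + 1L] <- 1L + sum(u[k] > row[1:2])
  }
  hypnogram(SLEEP_STATES[s], cfg$epoch_len_s)
}

cumsum_rows <- function(P) t(apply(P, 1, cumsum))

# shaped-noise spectrum template (two-sided, length m) for one state
state_spectrum_template <- function(par, m, fs) {
  f <- (0:(m - 1)) * fs / m
  f2 <- pmin(f, fs - f)                       # two-sided mirror
  S <- (1 / pmax(f2, 0.5))^par$slope
  if (!is.na(par$boost_hz) && par$boost_gain > 0) {
    ref <- (1 / pmax(par$boost_hz, 0.5))^par$slope
    S <- S + par$boost_gain * ref *
      exp(-(f2 - par$boost_hz)^2 / (2 * par$boost_bw_hz^2))
  }
  S[1] <- 0                                   # no DC
  S
}

# generate k columns of shaped Gaussian noise with spectrum S (unit RMS)
shaped_noise <- function(m, k, S) {
  wn <- matrix(stats::rnorm(m * k), m, k)
  ft <- stats::mvfft(wn) * sqrt(S)
  x <- Re(stats::mvfft(ft, inverse = TRUE)) / m
  x / rep(sqrt(colMeans(x^2)), each = m)
}

#' Synthesise EEG and EMG signals for a hypnogram
#'
#' Per epoch, EEG is 1/f-shaped Gaussian noise plus the state's band boost
#' (NREM: delta; REM: theta; wake: none) scaled to the state's RMS target with
#' mild lognormal epoch-to-epoch jitter; EMG is white noise at the state's
#' tone level (REM atonia lowest). Adjacent epochs are joined by a 0.25-s
#' equal-power crossfade so the signal is continuous at epoch boundaries.
#'
#' @param hyp a `Hypnogram` of WAKE/NREM/REM labels.
#' @param cfg a `"SimConfig"` consistent with `hyp`.
#' @return a two-channel `Recording` (`EEG1`, `EMG1`).
#' @export
synthesize_signals <- function(hyp, cfg) {
  validate_sim_config(cfg)
  if (abs(hyp$epoch_len_s - cfg$epoch_len_s) > 1e-9)
    stop("hypnogram epoch grid inconsistent with config")
  nep <- n_epochs(hyp)
  spe <- round(cfg$epoch_len_s * cfg$fs)
  fade <- round(0.25 * cfg$fs)
  nsamp <- nep * spe
  if (nep == 0) {
    return(recording(matrix(0, 2, 0), cfg$fs, c("EEG1", "EMG1"),
                     c("EEG", "EMG"), cfg$start_clock, cfg$lights_off_clock))
  }
  set.seed(mix_seed(cfg$seed, "signals"))
  m <- spe + fade                         # each segment spills into next epoch
  states <- hyp$labels
  eeg_seg <- matrix(0, m, nep)
  for (st in unique(states)) {
    par <- cfg$state_spectra[[st]]
    if (is.null(par)) stop("no state_spectra entry for ", st)
    cols <- which(states == st)
    S <- state_spectrum_template(par, m, cfg$fs)
    for (lo in seq(1, length(cols), by = 2048)) {
      cc <- cols[lo:min(length(cols), lo + 2047)]
      eeg_seg[, cc] <- shaped_noise(m, length(cc), S)
    }
    jit <- exp(stats::rnorm(length(cols), 0, par$rms_jitter_sd))
    eeg_seg[, cols] <- eeg_seg[, cols, drop = FALSE] *
      rep(par$eeg_rms * jit, each = m)
  }
  emg_levels <- vapply(states, function(st) cfg$state_spectra[[st]]$emg_rms, 0)
  emg_jit <- exp(stats::rnorm(nep, 0,
                              vapply(states, function(st)
                                cfg$state_spectra[[st]]$rms_jitter_sd, 0)))
  emg_seg <- matrix(stats::rnorm(m * nep), m, nep) *
    rep(emg_levels * emg_jit, each = m)
  eeg <- overlap_add(eeg_seg, spe, fade, nsamp)
  emg <- overlap_add(emg_seg, spe, fade, nsamp)
  recording(rbind(eeg, emg), cfg$fs, c("EEG1", "EMG1"), c("EEG", "EMG"),
            cfg$start_clock, cfg$lights_off_clock)
}

# equal-power crossfade overlap-add of segments (spe + fade samples each,
# epoch i placed at offset (i-1)*spe); returns a vector of nsamp samples
overlap_add <- function(segmat, spe, fade, nsamp) {
  m <- nrow(segmat); nep <- ncol(segmat)
  ramp <- sin(pi / 2 * (seq_len(fade) - 0.5) / fade)  # sin^2+cos^2 = 1
  up <- ramp; down <- rev(ramp)
  w <- rep(1, m); w[(m - fade + 1):m] <- down
  out <- numeric(nsamp + fade)
  for (i in seq_len(nep)) {
    seg <- segmat[, i] * w
    if (i > 1) seg[seq_len(fade)] <- seg[seq_len(fade)] * up
    o <- (i - 1) * spe
    out[(o + 1):(o + m)] <- out[(o + 1):(o + m)] + seg
  }
  out[seq_len(nsamp)]
}

# one period of the spike-wave template at unit period: asymmetric narrow
# positive spike plus a slow negative half-wave, demeaned
swd_template <- function(f0, fs, n_periods) {
  spp <- max(4L, round(fs / f0))              # samples per period
  ph <- (seq_len(spp) - 1) / spp              # phase in [0,1)
  sigma <- 0.008 * f0                         # 8-ms spike width in phase units
  spike <- exp(-(ph - 0.15)^2 / (2 * sigma^2))
  slow <- -0.55 * sin(pi * pmax(ph - 0.25, 0) / 0.75)
  per <- spike + slow
  per <- per - mean(per)
  rep(per, n_periods)
}

#' Inject spike-wave discharge events into a recording
#'
#' Adds periodic sharp-spike + slow-wave complexes at the configured
#' fundamental to every EEG channel. Event onsets fall inside epochs of the
#' state drawn from `swd_state_preference`; events are non-overlapping with at
#' least `swd_min_gap_s` between them, and each event's waveform is scaled to
#' `swd_amplitude_gain` times the local background RMS, with 0.1-s cosine
#' on/off ramps. The returned table is the ground truth.
#'
#' @param rec a `Recording` (modified copy returned).
#' @param hyp the ground-truth `Hypnogram` aligned with `rec`.
#' @param cfg a `"SimConfig"`.
#' @return `list(recording = <Recording>, events = <EventTable>)`.
#' @export
inject_swd_events <- function(rec, hyp, cfg) {
  validate_sim_config(cfg)
  if (abs(rec_duration(rec) - n_epochs(hyp) * hyp$epoch_len_s) > hyp$epoch_len_s)
    stop("recording and hypnogram are not aligned")
  ev <- place_events_only(hyp, cfg)
  if (!nrow(ev)) return(list(recording = rec, events = ev))
  starts <- ev$start_s; ends <- ev$end_s
  eeg_idx <- which(rec$channel_roles == "EEG")
  if (!length(eeg_idx)) stop("recording has no channel with role EEG")
  fs <- rec$fs
  ramp_n <- round(0.1 * fs)
  for (i in seq_along(starts)) {
    i0 <- floor(starts[i] * fs) + 1
    n_per <- ceiling((ends[i] - starts[i]) * cfg$swd_f0_hz)
    wav <- swd_template(cfg$swd_f0_hz, fs, n_per)
    wav <- wav[seq_len(min(length(wav), round((ends[i] - starts[i]) * fs)))]
    nw <- length(wav)
    if (i0 + nw - 1 > ncol(rec$signals)) nw <- ncol(rec$signals) - i0 + 1
    wav <- wav[seq_len(nw)]
    if (nw > 2 * ramp_n) {
      ramp <- sin(pi / 2 * seq_len(ramp_n) / ramp_n)^2
      wav[seq_len(ramp_n)] <- wav[seq_len(ramp_n)] * ramp
      wav[(nw - ramp_n + 1):nw] <- wav[(nw - ramp_n + 1):nw] * rev(ramp)
    }
    for (ch in eeg_idx) {
      seg <- rec$signals[ch, i0:(i0 + nw - 1)]
      amp <- cfg$swd_amplitude_gain * rms(seg) / rms(wav)
      rec$signals[ch, i0:(i0 + nw - 1)] <- seg + amp * wav
    }
  }
  list(recording = rec, events = ev)
}

#' Simulate a full recording with ground truth
#'
#' Convenience composition: [generate_hypnogram()], [synthesize_signals()],
#' [inject_swd_events()].
#'
#' @param cfg a `"SimConfig"`.
#' @param signals if `FALSE`, skip signal synthesis (hypnogram + ground-truth
#'   events only; event placement still honours state preference and spacing).
#' @return list with `hypnogram`, `events`, and (if requested) `recording`.
#' @export
simulate_recording <- function(cfg, signals = TRUE) {
  hyp <- generate_hypnogram(cfg)
  if (!signals) {
    ev <- place_events_only(hyp, cfg)
    return(list(hypnogram = hyp, events = ev, recording = NULL))
  }
  rec <- synthesize_signals(hyp, cfg)
  inj <- inject_swd_events(rec, hyp, cfg)
  list(hypnogram = hyp, events = inj$events, recording = inj$recording)
}

# ground-truth event placement (no signal involved); used both directly and
# by inject_swd_events, which then adds the waveforms
place_events_only <- function(hyp, cfg) {
  dur <- n_epochs(hyp) * hyp$epoch_len_s
  set.seed(mix_seed(cfg$seed, "swd"))
  n_ev <- cfg$swd_n_events %||%
    stats::rpois(1, cfg$swd_rate_per_h * dur / 3600)
  if (n_ev == 0) return(event_table())
  onset_states <- sample(SLEEP_STATES, n_ev, replace = TRUE,
                         prob = cfg$swd_state_preference)
  durs <- pmax(cfg$swd_min_duration_s,
               stats::rnorm(n_ev, cfg$swd_duration_s[[1]], cfg$swd_duration_s[[2]]))
  starts <- numeric(0); ends <- numeric(0); states <- character(0)
  by_state <- split(epoch_starts(hyp), hyp$labels)
  for (i in seq_len(n_ev)) {
    st <- onset_states[i]
    cand <- by_state[[st]]
    cand <- cand[cand + durs[i] <= dur]
    placed <- FALSE
    for (try in seq_len(200L)) {
      if (!length(cand)) break
      on <- cand[sample.int(length(cand), 1)] +
        stats::runif(1, 0, hyp$epoch_len_s)
      off <- on + durs[i]
      if (off > dur) next
      gap <- cfg$swd_min_gap_s
      if (!any(on < ends + gap & off > starts - gap)) {
        starts <- c(starts, on); ends <- c(ends, off); states <- c(states, st)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("SWD placement failed: could not place event ", i, " of ", n_ev,
           " after bounded retries (rate too high for the recording?)")
  }
  ord <- order(starts)
  event_table(starts[ord], ends[ord], onset_state = states[ord])
}

#' Simulate a cohort of animals
#'
#' Per-animal seeds derive deterministically from the master seed and the
#' animal's group label and index, so changing one group's size never
#' reshuffles another animal's data. A group's `rem_multiplier` scales the REM
#' dwell time (self-transition adjusted, row renormalised); `rate_multiplier`
#' scales `swd_rate_per_h`.
#'
#' @param group_specs list of specs: `list(label =, n =, rem_multiplier = 1,
#'   rate_multiplier = 1)`.
#' @param cfg baseline `"SimConfig"` shared by all animals.
#' @param seed master seed.
#' @param signals synthesise signals (`TRUE`) or ground truth only (`FALSE`).
#' @return list of animals, each `list(group, animal, config, hypnogram,
#'   events, recording)`.
#' @export
make_cohort <- function(group_specs, cfg = sim_config(), seed = 1,
                        signals = TRUE) {
  if (!length(group_specs)) stop("empty group_specs")
  out <- list()
  for (g in group_specs) {
    if (is.null(g$label) || is.null(g$n) || g$n < 1)
      stop("each group spec needs a label and n >= 1")
    remm <- g$rem_multiplier %||% 1
    ratem <- g$rate_multiplier %||% 1
    for (a in seq_len(g$n)) {
      ci <- cfg
      ci$state_transition_matrix <-
        scale_rem_dwell(cfg$state_transition_matrix, remm)
      ci$swd_rate_per_h <- cfg$swd_rate_per_h * ratem
      ci$seed <- mix_seed(seed, g$label, a)
      sim <- simulate_recording(ci, signals = signals)
      out[[length(out) + 1L]] <-
        list(group = g$label, animal = paste0(g$label, "_", a), config = ci,
             hypnogram = sim$hypnogram, events = sim$events,
             recording = sim$recording)
    }
  }
  out
}

# scale mean REM dwell time by m: dwell' = m * dwell, exits renormalised
scale_rem_dwell <- function(P, m) {
  if (m == 1) return(P)
  exit <- 1 - P[3, 3]
  new_exit <- min(1, exit / m)
  P[3, 1:2] <- P[3, 1:2] * new_exit / exit
  P[3, 3] <- 1 - sum(P[3, 1:2])
  P
}
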