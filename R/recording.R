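#' Multichannel EEG/EMG recording
#'
#' Container for a continuous polygraphic recording: a channels-by-samples
#' signal matrix in microvolts, a common sampling rate, per-channel roles
#' (`"EEG"` or `"EMG"`), and clock anchors for light-dark alignment.
#'
#' @param signals numeric matrix, channels x samples (microvolts). A vector is
#'   treated as a single channel.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one per channel.
#' @param channel_roles character vector over `{"EEG","EMG"}`, one per channel.
#' @param start_clock `"HH:MM"` clock time of the first sample.
#' @param lights_off_clock `"HH:MM"` clock time when lights go off (12:12 cycle).
#' @return an object of class `"Recording"`.
#' @export
recording <- function(signals, fs, channel_names = NULL, channel_roles = NULL,
                      start_clock = "07:00", lights_off_clock = "19:00") {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  nch <- nrow(signals)
  if (is.null(channel_roles)) channel_roles <- rep("EEG", nch)
  if (is.null(channel_names)) {
    channel_names <- paste0(channel_roles, seq_len(nch))
  }
  rec <- structure(
    list(signals = signals, fs = as.double(fs),
         channel_names = as.character(channel_names),
         channel_roles = toupper(channel_roles),
         start_clock = start_clock, lights_off_clock = lights_off_clock),
    class = "Recording")
  validate_recording(rec)
  rec
}

#' Validate a Recording
#'
#' Checks the type invariants: matrix signals, positive sampling rate,
#' per-channel names/roles, roles drawn from `{EEG, EMG}`.
#'
#' @param rec a `Recording`.
#' @return `rec`, invisibly; errors otherwise.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "Recording"))
  if (!is.matrix(rec$signals) || !is.numeric(rec$signals))
    stop("Recording signals must be a numeric channels x samples matrix")
  if (!is.finite(rec$fs) || rec$fs <= 0) stop("Recording fs must be > 0")
  nch <- nrow(rec$signals)
  if (length(rec$channel_names) != nch || length(rec$channel_roles) != nch)
    stop("channel_names/channel_roles must have one entry per channel")
  bad <- setdiff(unique(rec$channel_roles), c("EEG", "EMG"))
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  parse_clock(rec$start_clock); parse_clock(rec$lights_off_clock)
  invisible(rec)
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("Recording: %d channel(s) x %d samples @ %.4g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs, rec_duration(x)))
  cat(sprintf("  channels: %s\n",
              paste(sprintf("%s[%s]", x$channel_names, x$channel_roles),
                    collapse = ", ")))
  cat(sprintf("  start %s, lights off %s\n", x$start_clock, x$lights_off_clock))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `Recording`.
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$signals) / rec$fs

#' Extract one channel by name or role
#'
#' @param rec a `Recording`.
#' @param channel channel name; if `NULL`, the first channel with role `role`.
#' @param role role used when `channel` is `NULL`.
#' @return numeric vector of samples.
#' @export
get_channel <- function(rec, channel = NULL, role = "EEG") {
  if (is.null(channel)) {
    idx <- which(rec$channel_roles == role)
    if (!length(idx))
      stop("recording has no channel with role ", role)
    idx <- idx[1]
  } else {
    idx <- match(channel, rec$channel_names)
    if (is.na(idx)) stop("unknown channel: ", channel)
  }
  rec$signals[idx, ]
}
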