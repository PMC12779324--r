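# Minimal EDF (European Data Format) reader/writer: 16-bit integer samples
# with per-channel physical scaling, uniform sampling rate across channels.
# EDF+ annotations and vendor extensions are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

# pick a data-record duration (integer samples per record); EDF stores both
# the record duration and samples per record as ASCII numbers
edf_record_duration <- function(fs) {
  for (d in c(1, 2, 5, 10)) {
    if (abs(d * fs - round(d * fs)) < 1e-6) return(d)
  }
  stop("unsupported format: cannot represent fs = ", fs,
       " with an integer number of samples per record")
}

#' Write a Recording to an EDF file
#'
#' Samples are quantised to 16 bits over each channel's physical range; the
#' recording start clock goes into the EDF start-time field; channel roles are
#' encoded in the signal labels (`"EEG name"` / `"EMG name"`). The recording
#' is truncated to a whole number of data records (a warning is emitted if any
#' samples are dropped).
#'
#' @param rec a `Recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  nch <- nrow(rec$signals)
  dur <- edf_record_duration(rec$fs)
  spr <- round(rec$fs * dur)
  n_rec <- floor(ncol(rec$signals) / spr)
  if (n_rec * spr < ncol(rec$signals))
    warning("truncating ", ncol(rec$signals) - n_rec * spr,
            " trailing sample(s) to a whole EDF record")
  start_h <- parse_clock(rec$start_clock)
  hh <- floor(start_h); mm <- round((start_h - hh) * 60)
  labels <- paste(rec$channel_roles, rec$channel_names)
  pmin_v <- numeric(nch); pmax_v <- numeric(nch)
  for (ch in seq_len(nch)) {
    x <- rec$signals[ch, seq_len(n_rec * spr)]
    lo <- if (length(x)) min(x) else -1
    hi <- if (length(x)) max(x) else 1
    if (hi - lo < 1e-9) { lo <- lo - 1; hi <- hi + 1 }
    pmin_v[ch] <- lo; pmax_v[ch] <- hi
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                       # patient id (synthetic)
  wr(paste("Startdate 01-JAN-2001", "X", "X", "X"), 80)
  wr("01.01.01", 8)
  wr(sprintf("%02d.%02d.00", hh, mm), 8)
  wr(256 * (1 + nch), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(format(dur), 8)
  wr(nch, 4)
  for (lab in labels) wr(lab, 16)
  for (ch in seq_len(nch)) wr("", 80)     # transducer
  for (ch in seq_len(nch)) wr("uV", 8)
  for (ch in seq_len(nch)) wr(format(signif(pmin_v[ch], 8)), 8)
  for (ch in seq_len(nch)) wr(format(signif(pmax_v[ch], 8)), 8)
  for (ch in seq_len(nch)) wr("-32768", 8)
  for (ch in seq_len(nch)) wr("32767", 8)
  for (ch in seq_len(nch)) wr("", 80)     # prefiltering
  for (ch in seq_len(nch)) wr(spr, 8)
  for (ch in seq_len(nch)) wr("", 32)
  # parse back the header's physical ranges so quantisation is self-consistent
  pmin_h <- as.numeric(format(signif(pmin_v, 8)))
  pmax_h <- as.numeric(format(signif(pmax_v, 8)))
  dig <- matrix(0L, nch, n_rec * spr)
  for (ch in seq_len(nch)) {
    x <- rec$signals[ch, seq_len(n_rec * spr)]
    d <- round((x - pmin_h[ch]) / (pmax_h[ch] - pmin_h[ch]) * 65535 - 32768)
    dig[ch, ] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  for (r in seq_len(n_rec)) {
    s0 <- (r - 1) * spr
    for (ch in seq_len(nch)) {
      writeBin(dig[ch, (s0 + 1):(s0 + spr)], con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a Recording from an EDF file
#'
#' Supports plain EDF with one uniform sampling rate across channels. Channel
#' roles are recovered from the `EEG`/`EMG` label prefix (anything else is
#' treated as EEG with a warning).
#'
#' @param path EDF file path.
#' @param lights_off_clock lights-off clock anchor, not stored in EDF
#'   (default `"19:00"`).
#' @return a `Recording`.
#' @export
read_recording <- function(path, lights_off_clock = "19:00") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                    # version
  rd(80); rd(80); rd(8)                    # ids, date
  start_time <- rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)            # units
  pmin_v <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  pmax_v <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmin_v <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dmax_v <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1)
    stop("unsupported format: channels have mixed sampling rates")
  spr <- spr[1]
  fs <- spr / rec_dur
  sig <- matrix(0, nch, n_rec * spr)
  for (r in seq_len(n_rec)) {
    s0 <- (r - 1) * spr
    for (ch in seq_len(nch)) {
      d <- readBin(con, integer(), n = spr, size = 2, endian = "little")
      sig[ch, (s0 + 1):(s0 + spr)] <-
        (d + 32768) / (dmax_v[ch] - dmin_v[ch]) *
        (pmax_v[ch] - pmin_v[ch]) + pmin_v[ch]
    }
  }
  roles <- ifelse(grepl("^EMG", labels), "EMG",
                  ifelse(grepl("^EEG", labels), "EEG", NA))
  if (anyNA(roles)) {
    warning("channel label(s) without EEG/EMG prefix treated as EEG")
    roles[is.na(roles)] <- "EEG"
  }
  names_ <- trimws(sub("^(EEG|EMG)\\s*", "", labels))
  names_[names_ == ""] <- paste0("ch", which(names_ == ""))
  tm <- strsplit(start_time, ".", fixed = TRUE)[[1]]
  start_clock <- sprintf("%02d:%02d", as.integer(tm[1]), as.integer(tm[2]))
  recording(sig, fs, names_, roles, start_clock, lights_off_clock)
}
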