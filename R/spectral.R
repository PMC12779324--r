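#' Canonical frequency-band scheme
#'
#' Half-open bands `[lo_hz, hi_hz)`. Defaults: delta `[1,5)`, theta `[5,10)`,
#' sigma `[10,16)`, beta `[16,30)`, gamma `[30,48)`. Theta coincides with the
#' 5-10 Hz SWD fundamental range; gamma stops below 50 Hz mains. All edges are
#' overridable.
#'
#' @param bands named list of `c(lo, hi)` pairs in Hz.
#' @return a `data.frame` of class `"BandScheme"` with columns
#'   `band`, `lo_hz`, `hi_hz`.
#' @export
band_scheme <- function(bands = list(delta = c(1, 5), theta = c(5, 10),
                                     sigma = c(10, 16), beta = c(16, 30),
                                     gamma = c(30, 48))) {
  df <- data.frame(band = names(bands),
                   lo_hz = vapply(bands, `[`, 0, 1),
                   hi_hz = vapply(bands, `[`, 0, 2),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (any(df$lo_hz >= df$hi_hz)) stop("band edges must satisfy lo < hi")
  df <- df[order(df$lo_hz), , drop = FALSE]
  if (nrow(df) > 1 && any(df$lo_hz[-1] < df$hi_hz[-nrow(df)]))
    stop("bands must be non-overlapping and strictly increasing")
  class(df) <- c("BandScheme", "data.frame")
  df
}

hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Welch PSD for a set of equal-length segments laid out as columns.
# Returns one-sided PSD (uV^2/Hz) per column; density scaling such that
# sum(psd) * df approximates segment variance (Parseval).
psd_columns <- function(segmat, fs, window = hann(nrow(segmat)),
                        nfft = nrow(segmat)) {
  nwin <- nrow(segmat)
  segmat <- segmat * window
  if (nfft > nwin)          # zero-padding: finer grid for peak localisation
    segmat <- rbind(segmat, matrix(0, nfft - nwin, ncol(segmat)))
  ft <- stats::mvfft(segmat)
  nfreq <- floor(nfft / 2) + 1
  p <- (Mod(ft[seq_len(nfreq), , drop = FALSE])^2) / (fs * sum(window^2))
  # one-sided: double interior bins (not DC; not Nyquist when nfft is even)
  last_dbl <- if (nfft %% 2 == 0) nfreq - 1 else nfreq
  if (last_dbl >= 2) p[2:last_dbl, ] <- 2 * p[2:last_dbl, , drop = FALSE]
  list(freqs = (seq_len(nfreq) - 1) * fs / nfft, power = p)
}

new_psd <- function(freqs, power, n_segments, window_s) {
  structure(list(freqs = freqs, power = pmax(power, 0),
                 n_segments = n_segments, window_s = window_s),
            class = "PsdEstimate")
}

#' @export
print.PsdEstimate <- function(x, ...) {
  cat(sprintf("PsdEstimate: %d bins, 0-%.4g Hz (df = %.3g Hz), %d segment(s), %g-s window\n",
              length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1],
              x$n_segments, x$window_s))
  invisible(x)
}

#' Welch power spectral density
#'
#' Segment-averaged one-sided Hann periodogram. The estimate is density-scaled:
#' integrating it over `[0, fs/2]` recovers the signal variance (Parseval,
#' within sampling error for stationary noise).
#'
#' @param x single-channel signal (numeric vector), microvolts.
#' @param fs sampling rate, Hz.
#' @param window_s window length in seconds (default 2, giving ~0.5 Hz
#'   resolution; resolves 5-10 Hz SWD fundamentals and their harmonics within a
#'   5-s epoch).
#' @param overlap_fraction fractional overlap between consecutive windows
#'   (default 0.5), in `[0, 1)`.
#' @param demean subtract the signal mean first (default `TRUE`).
#' @return a `"PsdEstimate"`: list with `freqs` (Hz), `power` (uV^2/Hz),
#'   `n_segments`, `window_s`.
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap_fraction = 0.5,
                      demean = TRUE) {
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1)
  nwin <- round(window_s * fs)
  if (length(x) < nwin)
    stop("segment shorter than one window (", length(x), " < ", nwin, " samples)")
  if (demean) x <- x - mean(x)
  hop <- max(1L, round(nwin * (1 - overlap_fraction)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  segmat <- matrix(x[outer(0:(nwin - 1L), starts, `+`)], nrow = nwin)
  pc <- psd_columns(segmat, fs)
  new_psd(pc$freqs, rowMeans(pc$power), length(starts), window_s)
}

#' Band power by trapezoidal integration of a PSD
#'
#' Integrates the PSD over each half-open band `[lo, hi)` by the trapezoid
#' rule, linearly interpolating the PSD at the band edges so that band power is
#' exactly additive over a partition of a band.
#'
#' @param psd a `"PsdEstimate"`.
#' @param scheme a `"BandScheme"`.
#' @param normalization `"absolute"` (uV^2) or `"relative-to-total"` (fractions
#'   summing to 1 over the scheme).
#' @return named numeric vector of band powers, with attribute
#'   `normalization`; classed `"BandPowerTable"`.
#' @export
band_power <- function(psd, scheme = band_scheme(),
                       normalization = c("absolute", "relative-to-total")) {
  normalization <- match.arg(normalization)
  fmax <- max(psd$freqs)
  if (any(scheme$hi_hz > fmax + 1e-9))
    warning("band edge above PSD range; clipping at ", signif(fmax, 4), " Hz")
  out <- vapply(seq_len(nrow(scheme)), function(i) {
    integrate_psd(psd$freqs, psd$power, scheme$lo_hz[i], min(scheme$hi_hz[i], fmax))
  }, 0)
  names(out) <- scheme$band
  if (normalization == "relative-to-total") {
    tot <- sum(out)
    if (tot <= 0) stop("total band power is zero; relative mode undefined")
    out <- out / tot
  }
  structure(out, normalization = normalization,
            class = c("BandPowerTable", class(out)))
}

# trapezoid integral of piecewise-linear PSD over [lo, hi]
integrate_psd <- function(freqs, power, lo, hi) {
  if (hi <= lo) return(0)
  lo <- max(lo, freqs[1]); hi <- min(hi, freqs[length(freqs)])
  if (hi <= lo) return(0)
  grid <- sort(unique(c(lo, hi, freqs[freqs > lo & freqs < hi])))
  vals <- stats::approx(freqs, power, xout = grid, rule = 2)$y
  sum(diff(grid) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}

# split one channel into full epochs (trailing partial epoch dropped) as a
# samples x epochs matrix
epoch_matrix <- function(x, fs, epoch_len_s) {
  spe <- round(epoch_len_s * fs)
  nep <- floor(length(x) / spe)
  if (nep < 1) stop("recording shorter than one epoch")
  matrix(x[seq_len(nep * spe)], nrow = spe)
}

# Welch PSD per epoch, vectorised: all windows of all epochs go through one
# mvfft per chunk. Returns list(freqs, power = bins x epochs matrix).
epoch_psds <- function(x, fs, epoch_len_s, window_s = 2, overlap_fraction = 0.5,
                       chunk = 4096L) {
  em <- epoch_matrix(x, fs, epoch_len_s)
  em <- sweep(em, 2, colMeans(em))
  spe <- nrow(em); nep <- ncol(em)
  nwin <- round(window_s * fs)
  if (spe < nwin) stop("epoch shorter than one Welch window")
  hop <- max(1L, round(nwin * (1 - overlap_fraction)))
  starts <- seq(1L, spe - nwin + 1L, by = hop)
  w <- hann(nwin)
  idx <- outer(0:(nwin - 1L), starts, `+`)  # window sample index within epoch
  nfreq <- floor(nwin / 2) + 1
  pw <- matrix(0, nfreq, nep)
  nw <- length(starts)
  for (lo in seq(1L, nep, by = chunk)) {
    cols <- lo:min(nep, lo + chunk - 1L)
    seg <- matrix(em[as.vector(idx) +
                       rep((cols - 1L) * spe, each = length(idx))],
                  nrow = nwin)
    pc <- psd_columns(seg, fs, w)
    # columns are grouped per epoch (nw consecutive windows each)
    p3 <- aperm(array(pc$power, c(nfreq, nw, length(cols))), c(2, 1, 3))
    pw[, cols] <- colMeans(p3, dims = 1)
  }
  list(freqs = (seq_len(nfreq) - 1) * fs / nwin, power = pw,
       n_segments = length(starts))
}

#' Per-epoch band powers
#'
#' Splits a channel into consecutive epochs (trailing partial epoch dropped),
#' estimates a Welch PSD per epoch and integrates it over the band scheme.
#'
#' @param rec a `Recording`.
#' @param channel channel name (default: first EEG channel).
#' @param epoch_len_s epoch length, seconds (default 5).
#' @param scheme a `"BandScheme"`.
#' @param window_s,overlap_fraction Welch parameters (see [welch_psd()]).
#' @return matrix of band powers, epochs x bands (uV^2).
#' @export
epoch_band_powers <- function(rec, channel = NULL, epoch_len_s = 5,
                              scheme = band_scheme(), window_s = 2,
                              overlap_fraction = 0.5) {
  if (any(scheme$hi_hz > rec$fs / 2 + 1e-9))
    stop("band scheme exceeds Nyquist frequency")
  x <- get_channel(rec, channel)
  ep <- epoch_psds(x, rec$fs, epoch_len_s, window_s, overlap_fraction)
  t(apply_bands(ep$freqs, ep$power, scheme))
}

# integrate a bins x epochs power matrix over bands -> bands x epochs
apply_bands <- function(freqs, power, scheme) {
  out <- matrix(0, nrow(scheme), ncol(power),
                dimnames = list(scheme$band, NULL))
  for (i in seq_len(nrow(scheme))) {
    out[i, ] <- band_integral_cols(freqs, power, scheme$lo_hz[i], scheme$hi_hz[i])
  }
  out
}

# vectorised trapezoid integral over [lo, hi] for each column
band_integral_cols <- function(freqs, power, lo, hi) {
  lo <- max(lo, freqs[1]); hi <- min(hi, freqs[length(freqs)])
  if (hi <= lo) return(rep(0, ncol(power)))
  grid <- sort(unique(c(lo, hi, freqs[freqs > lo & freqs < hi])))
  # linear interpolation of every column at lo and hi
  interp_col <- function(f0) {
    j <- findInterval(f0, freqs, all.inside = TRUE)
    w <- (f0 - freqs[j]) / (freqs[j + 1] - freqs[j])
    power[j, ] * (1 - w) + power[j + 1, ] * w
  }
  inner <- freqs > lo & freqs < hi
  vals <- rbind(interp_col(lo), power[inner, , drop = FALSE], interp_col(hi))
  dg <- diff(grid)
  colSums(vals[-nrow(vals), , drop = FALSE] * dg +
            (vals[-1, , drop = FALSE] - vals[-nrow(vals), , drop = FALSE]) * dg / 2)
}

#' Average spectrum over epochs carrying a label
#'
#' Mean of per-epoch Welch PSDs over the epochs whose hypnogram label (or
#' logical mask entry) matches `target` — e.g. the average spectrum during all
#' SWD epochs, or during REM/NREM/wake.
#'
#' @param rec a `Recording`.
#' @param labels a `Hypnogram`, a character vector of per-epoch labels, or a
#'   logical per-epoch mask.
#' @param target label to select (ignored when `labels` is logical).
#' @param channel channel name (default first EEG).
#' @param epoch_len_s epoch length in seconds; defaults to the hypnogram's.
#' @param window_s,overlap_fraction Welch parameters.
#' @return a `"PsdEstimate"` (mean of the selected epochs' PSDs).
#' @export
average_state_spectrum <- function(rec, labels, target = "SWD", channel = NULL,
                                   epoch_len_s = NULL, window_s = 2,
                                   overlap_fraction = 0.5) {
  if (inherits(labels, "Hypnogram")) {
    epoch_len_s <- epoch_len_s %||% labels$epoch_len_s
    labels <- labels$labels
  }
  epoch_len_s <- epoch_len_s %||% 5
  x <- get_channel(rec, channel)
  ep <- epoch_psds(x, rec$fs, epoch_len_s, window_s, overlap_fraction)
  nep <- ncol(ep$power)
  sel <- if (is.logical(labels)) labels else labels == target
  if (length(sel) < nep) {
    stop("labels cover fewer epochs (", length(sel), ") than the recording (",
         nep, ")")
  }
  sel <- sel[seq_len(nep)]
  if (!any(sel))
    stop("empty selection: no epochs with label '", target, "'")
  new_psd(ep$freqs, rowMeans(ep$power[, sel, drop = FALSE]),
          ep$n_segments * sum(sel), window_s)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, implemented as a
#' high-pass/low-pass cascade for numerical robustness with narrow low-frequency
#' bands such as delta at a 250.4 Hz sampling rate. Output length equals input
#' length; stop-band attenuation exceeds 20 dB one octave outside the passband.
#'
#' @param x signal vector.
#' @param lo_hz,hi_hz passband edges, `0 < lo < hi < fs/2`.
#' @param fs sampling rate, Hz.
#' @param order Butterworth order per edge (default 4).
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, lo_hz, hi_hz, fs, order = 4) {
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs / 2))
    stop("invalid band: need 0 < lo < hi < fs/2")
  hp <- signal::butter(order, lo_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, hi_hz / (fs / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, y)
}
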