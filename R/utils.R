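#' @keywords internal
"_PACKAGE"

# Vigilance-state vocabulary used throughout. SWD and UNSCORED are reserved for
# masked seizure epochs and degenerate (flatline) epochs respectively.
STATE_LEVELS <- c("WAKE", "NREM", "REM", "SWD", "UNSCORED")
SLEEP_STATES <- c("WAKE", "NREM", "REM")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' Fixed integer mixing (multiplicative hash, 31-bit result) so that per-animal
#' or per-operation seeds are stable: adding an animal to one group never
#' reshuffles another animal's data.
#'
#' @param seed master seed (integer).
#' @param ... integers and/or short strings identifying the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
mix_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.double(p)) {
      h <- (h * 48271 + v + 1) %% 2147483647
    }
  }
  as.integer(h)
}

#' Parse a clock time
#'
#' @param x `"HH:MM"` string.
#' @return hours past midnight as a double in `[0, 24)`.
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) {
    stopifnot(x >= 0, x < 24)
    return(as.double(x))
  }
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3) stop("clock time must be 'HH:MM', got: ", x)
  h <- as.integer(m[2]); mn <- as.integer(m[3])
  if (h > 23 || mn > 59) stop("invalid clock time: ", x)
  h + mn / 60
}

#' Is a clock hour inside the dark (lights-off) phase?
#'
#' The cycle is 12:12; dark spans `[lights_off, lights_off + 12)` modulo 24.
#'
#' @param hour_of_day hours past midnight (vectorised).
#' @param lights_off_clock `"HH:MM"` or numeric hours.
#' @return logical vector.
#' @export
is_dark_phase <- function(hour_of_day, lights_off_clock = "19:00") {
  off <- parse_clock(lights_off_clock)
  ((hour_of_day - off) %% 24) < 12
}

rms <- function(x) sqrt(mean(x^2))
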