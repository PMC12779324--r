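# CSV dialects: hypnogram = (epoch_index, start_s, label); events =
# (start_s, end_s, duration_s, onset_state, transition_flag). Times are
# decimal seconds from recording start on half-open intervals.

#' Write a hypnogram to CSV
#' @param hyp a `Hypnogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  validate_hypnogram(hyp)
  df <- data.frame(epoch_index = seq_len(n_epochs(hyp)) - 1L,
                   start_s = epoch_starts(hyp),
                   label = hyp$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' The epoch length is recovered from the `start_s` grid (a single epoch needs
#' `epoch_len_s`).
#'
#' @param path CSV path in the [write_hypnogram()] dialect.
#' @param epoch_len_s fallback epoch length when the file has < 2 epochs.
#' @return a `Hypnogram`.
#' @export
read_hypnogram <- function(path, epoch_len_s = 5) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "start_s", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("hypnogram CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[order(df$epoch_index), , drop = FALSE]
  if (nrow(df) >= 2) {
    steps <- diff(df$start_s)
    if (max(abs(steps - steps[1])) > 1e-6)
      stop("hypnogram CSV epoch grid is not uniform")
    epoch_len_s <- steps[1]
  }
  hypnogram(df$label, epoch_len_s)
}

#' Write an event table to CSV
#' @param events an `EventTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' Rows are sorted by onset and re-validated (non-overlap, duration
#' consistency); violations raise errors naming the offending rows.
#'
#' @param path CSV path in the [write_events()] dialect.
#' @return an `EventTable`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "onset_state", "transition_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  event_table(df$start_s, df$end_s, onset_state = df$onset_state,
              transition_flag = df$transition_flag)
}

#' Write an AnimalSummary (or any summary list) to JSON
#'
#' Missing values are written as JSON `null`, never silently as 0.
#'
#' @param x an `"AnimalSummary"` or plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  if (inherits(x, "AnimalSummary")) {
    x$events <- as.data.frame(x$events)
    class(x) <- "list"
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Write a SimConfig to a YAML file
#'
#' The file carries an explicit `schema_version` field.
#'
#' @param cfg a `"SimConfig"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  x <- unclass(cfg)
  x$state_transition_matrix <-
    lapply(seq_len(3), function(i) as.numeric(cfg$state_transition_matrix[i, ]))
  x$swd_state_preference <- as.numeric(cfg$swd_state_preference)
  x$swd_duration_s <- as.numeric(cfg$swd_duration_s)
  x <- c(list(schema_version = 1), x)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a SimConfig from a YAML file
#' @param path YAML path written by [write_sim_config()].
#' @return a validated `"SimConfig"`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- yaml::read_yaml(path)
  if (is.null(x$schema_version) || x$schema_version != 1)
    stop("unsupported config schema_version: ",
         x$schema_version %||% "<missing>")
  P <- do.call(rbind, x$state_transition_matrix)
  dimnames(P) <- list(SLEEP_STATES, SLEEP_STATES)
  sim_config(
    duration_s = x$duration_s, epoch_len_s = x$epoch_len_s, fs = x$fs,
    state_transition_matrix = P,
    dark_phase_wake_bias = x$dark_phase_wake_bias,
    state_spectra = x$state_spectra,
    swd_rate_per_h = x$swd_rate_per_h,
    swd_n_events = x$swd_n_events,
    swd_duration_s = unlist(x$swd_duration_s),
    swd_min_duration_s = x$swd_min_duration_s,
    swd_min_gap_s = x$swd_min_gap_s,
    swd_f0_hz = x$swd_f0_hz,
    swd_amplitude_gain = x$swd_amplitude_gain,
    swd_state_preference = stats::setNames(unlist(x$swd_state_preference),
                                           SLEEP_STATES),
    start_clock = x$start_clock, lights_off_clock = x$lights_off_clock,
    seed = x$seed)
}
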