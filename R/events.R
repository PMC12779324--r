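#' Table of SWD events
#'
#' A sorted, non-overlapping set of events on half-open intervals
#' `[start_s, end_s)` in seconds from recording start, with the vigilance state
#' at onset and a wake-to-NREM transition flag (filled by
#' [assign_event_states()]).
#'
#' @param start_s,end_s numeric vectors of onsets/offsets in seconds.
#' @param onset_state state at onset (`WAKE`/`NREM`/`REM`/`UNSCORED`).
#' @param transition_flag logical: SWD initiated at a wake-NREM transition.
#' @param sort sort rows by `start_s` before validating (default `TRUE`).
#' @return a `data.frame` of class `"EventTable"` with columns `start_s`,
#'   `end_s`, `duration_s`, `onset_state`, `transition_flag`.
#' @export
event_table <- function(start_s = numeric(), end_s = numeric(),
                        onset_state = rep("UNSCORED", length(start_s)),
                        transition_flag = rep(FALSE, length(start_s)),
                        sort = TRUE) {
  df <- data.frame(start_s = as.double(start_s), end_s = as.double(end_s),
                   duration_s = as.double(end_s) - as.double(start_s),
                   onset_state = as.character(onset_state),
                   transition_flag = as.logical(transition_flag),
                   stringsAsFactors = FALSE)
  if (sort && nrow(df) > 1) df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("EventTable", "data.frame")
  validate_events(df)
  df
}

#' Validate an EventTable
#'
#' Enforces `start_s < end_s` per row, rows sorted by onset, no overlapping
#' events, and `duration_s = end_s - start_s` (1e-9 tolerance). Violations name
#' the offending rows.
#'
#' @param ev an `EventTable`.
#' @return `ev`, invisibly.
#' @export
validate_events <- function(ev) {
  stopifnot(inherits(ev, "EventTable"))
  need <- c("start_s", "end_s", "duration_s", "onset_state", "transition_flag")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("EventTable missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(ev)) return(invisible(ev))
  bad <- which(ev$start_s >= ev$end_s)
  if (length(bad)) stop("events with start_s >= end_s at row(s): ",
                        paste(bad, collapse = ", "))
  if (is.unsorted(ev$start_s)) stop("events are not sorted by start_s")
  bad <- which(abs(ev$duration_s - (ev$end_s - ev$start_s)) > 1e-9)
  if (length(bad)) stop("duration_s inconsistent at row(s): ",
                        paste(bad, collapse = ", "))
  if (nrow(ev) > 1) {
    ov <- which(ev$start_s[-1] < ev$end_s[-nrow(ev)])
    if (length(ov)) stop("overlapping events at row pair(s): ",
                         paste(sprintf("%d/%d", ov, ov + 1), collapse = ", "))
  }
  bad <- setdiff(unique(ev$onset_state), STATE_LEVELS)
  if (length(bad)) stop("unknown onset_state value(s): ", paste(bad, collapse = ", "))
  invisible(ev)
}

#' @export
print.EventTable <- function(x, ...) {
  cat(sprintf("EventTable: %d event(s), total %.1f s\n",
              nrow(x), sum(x$duration_s)))
  NextMethod()
}
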