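#' Segment a hypnogram into bouts
#'
#' Maximal runs of identical labels. Bouts tile the hypnogram exactly and
#' consecutive bouts have different states.
#'
#' @param hyp a `Hypnogram`.
#' @return data.frame with columns `state`, `start_epoch`, `end_epoch`
#'   (half-open, 0-based) and `duration_s`.
#' @export
segment_bouts <- function(hyp) {
  if (!n_epochs(hyp)) {
    return(data.frame(state = character(), start_epoch = integer(),
                      end_epoch = integer(), duration_s = numeric()))
  }
  r <- rle(hyp$labels)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  data.frame(state = r$values, start_epoch = as.integer(s),
             end_epoch = as.integer(e),
             duration_s = r$lengths * hyp$epoch_len_s)
}

#' Mask SWD event epochs onto a hypnogram
#'
#' Every epoch overlapping any event is relabeled `SWD`, so that seizure time
#' is excluded from the state minute totals.
#'
#' @param hyp a `Hypnogram`.
#' @param events an `EventTable`.
#' @return a `Hypnogram` with `SWD` labels applied.
#' @export
mask_swd_epochs <- function(hyp, events) {
  validate_events(events)
  if (!nrow(events) || !n_epochs(hyp)) return(hyp)
  T <- hyp$epoch_len_s
  lab <- hyp$labels
  for (i in seq_len(nrow(events))) {
    k0 <- max(0L, floor(events$start_s[i] / T))
    k1 <- min(n_epochs(hyp) - 1L, ceiling(events$end_s[i] / T) - 1L)
    if (k1 >= k0) lab[(k0:k1) + 1L] <- "SWD"
  }
  hypnogram(lab, T)
}

# hour of day for each epoch start
epoch_hours <- function(hyp, start_clock) {
  (parse_clock(start_clock) + epoch_starts(hyp) / 3600) %% 24
}

state_block_one <- function(hyp, sel = rep(TRUE, n_epochs(hyp))) {
  epl <- hyp$epoch_len_s
  out <- list()
  sub_labels <- hyp$labels[sel]
  bouts <- segment_bouts(hypnogram(sub_labels, epl))
  for (st in c(SLEEP_STATES, "SWD", "UNSCORED")) {
    b <- bouts[bouts$state == st, , drop = FALSE]
    out[[st]] <- list(
      total_min = sum(sub_labels == st) * epl / 60,
      n_bouts = nrow(b),
      mean_bout_s = if (nrow(b)) mean(b$duration_s) else NA_real_)
  }
  out
}

#' State totals with SWD masking and light-dark/hourly aggregation
#'
#' Epochs overlapping any SWD event are masked to `SWD` before totals are
#' computed (seizure time is excluded from the state minutes, wake included).
#' Totals, bout counts and mean bout durations are reported over the full
#' recording, per 12-h light/dark phase, and as per-hour-of-day vectors.
#'
#' @param hyp the scored `Hypnogram` (pre-masking).
#' @param events SWD `EventTable` (may be empty).
#' @param start_clock,lights_off_clock clock anchors (`"HH:MM"`).
#' @return list with elements `total` (per-state block over the whole
#'   recording), `light`/`dark` (per-phase blocks), `hourly_min` (state x 24
#'   matrix of minutes by hour of day), `coverage` (fraction of each hour bin
#'   actually recorded, 24-vector), `recording_min`.
#' @export
state_totals <- function(hyp, events = event_table(), start_clock = "07:00",
                         lights_off_clock = "19:00") {
  masked <- mask_swd_epochs(hyp, events)
  nep <- n_epochs(masked)
  epl <- masked$epoch_len_s
  hod <- epoch_hours(masked, start_clock)
  dark <- is_dark_phase(hod, lights_off_clock)
  hour_bin <- floor(hod) %% 24
  states <- c(SLEEP_STATES, "SWD", "UNSCORED")
  hourly <- matrix(0, length(states), 24,
                   dimnames = list(states, sprintf("h%02d", 0:23)))
  for (st in states) {
    tab <- tapply(rep(epl / 60, nep)[masked$labels == st],
                  factor(hour_bin[masked$labels == st], levels = 0:23), sum)
    hourly[st, ] <- ifelse(is.na(tab), 0, tab)
  }
  coverage <- as.vector(table(factor(hour_bin, levels = 0:23))) * epl / 3600
  list(total = state_block_one(masked),
       light = state_block_one(masked, !dark),
       dark = state_block_one(masked, dark),
       hourly_min = hourly,
       coverage = coverage,
       recording_min = nep * epl / 60)
}

#' Annotate events with onset state and transition flag
#'
#' `onset_state` is the label of the (pre-masking) hypnogram epoch containing
#' the event onset. `transition_flag` is `TRUE` iff the onset state is NREM,
#' the enclosing NREM bout begins within `transition_window_s` after a WAKE
#' bout ends, and the onset falls within `transition_window_s` of that bout
#' start — an SWD initiating at a wake-NREM transition.
#'
#' @param events an `EventTable`.
#' @param hyp the original (pre-masking) `Hypnogram`; must cover all events.
#' @param transition_window_s window length in seconds (default 30, i.e. six
#'   5-s scoring epochs).
#' @return the annotated `EventTable`.
#' @export
assign_event_states <- function(events, hyp, transition_window_s = 30) {
  validate_events(events)
  if (!nrow(events)) return(events)
  T <- hyp$epoch_len_s
  dur <- n_epochs(hyp) * T
  if (any(events$start_s >= dur))
    stop("event onset beyond hypnogram coverage")
  bouts <- segment_bouts(hyp)
  bout_start_s <- bouts$start_epoch * T
  bout_end_s <- bouts$end_epoch * T
  onset_epoch <- floor(events$start_s / T)
  events$onset_state <- hyp$labels[onset_epoch + 1L]
  flag <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (events$onset_state[i] != "NREM") next
    bi <- findInterval(events$start_s[i], bout_start_s)
    t0 <- bout_start_s[bi]
    if (events$start_s[i] - t0 > transition_window_s) next
    wk <- which(bouts$state == "WAKE" & bout_end_s <= t0 + 1e-9 &
                  t0 - bout_end_s <= transition_window_s)
    flag[i] <- length(wk) > 0
  }
  events$transition_flag <- flag
  events
}

#' Percentages of SWD onsets per vigilance state
#'
#' @param events an annotated `EventTable` (see [assign_event_states()]).
#' @return named vector of percentages over (WAKE, NREM, REM), summing to 100;
#'   states with no events report 0. Errors on an empty table.
#' @export
state_event_proportions <- function(events) {
  validate_events(events)
  if (!nrow(events)) stop("empty event table: proportions undefined")
  n <- vapply(SLEEP_STATES, function(st) sum(events$onset_state == st), 0)
  100 * n / sum(n)
}

#' Event counts per hour of day
#'
#' Events are assigned to the clock-hour bin containing their onset
#' (half-open bins; an onset exactly on a boundary goes to the later bin).
#'
#' @param events an `EventTable`.
#' @param start_clock clock time of recording start (`"HH:MM"`).
#' @return integer 24-vector named `h00`..`h23` (hour of day).
#' @export
hourly_counts <- function(events, start_clock = "07:00") {
  validate_events(events)
  out <- integer(24)
  names(out) <- sprintf("h%02d", 0:23)
  if (!nrow(events)) return(out)
  hod <- (parse_clock(start_clock) + events$start_s / 3600) %% 24
  tab <- table(factor(floor(hod) %% 24, levels = 0:23))
  out[] <- as.integer(tab)
  out
}

#' Split an hour-of-day metric into light and dark phases
#'
#' @param hourly a 24-vector indexed by hour of day (0-23).
#' @param lights_off_clock `"HH:MM"`; dark spans the 12 h from lights off.
#' @return `c(light = , dark = )` sums.
#' @export
phase_split <- function(hourly, lights_off_clock = "19:00") {
  stopifnot(length(hourly) == 24)
  dark <- is_dark_phase(0:23 + 0.5, lights_off_clock)
  c(light = sum(hourly[!dark]), dark = sum(hourly[dark]))
}

#' Express a treatment value as percent of baseline
#'
#' @param value_treatment,value_baseline numeric scalars; baseline must be > 0.
#' @return `100 * value_treatment / value_baseline`.
#' @export
percent_of_baseline <- function(value_treatment, value_baseline) {
  if (!is.finite(value_baseline) || value_baseline <= 0)
    stop("undefined result: baseline must be > 0")
  100 * value_treatment / value_baseline
}

#' Per-animal 24-h summary
#'
#' Assembles the full per-animal metric set: SWD count / mean / total
#' duration, hourly event counts with light-dark split, per-state minutes and
#' bout statistics (24-h, per phase, per hour) with SWD masking, onset-state
#' percentages, and the proportion of SWDs initiated at wake-NREM transitions
#' (overall and among NREM-onset events).
#'
#' @param hyp the scored `Hypnogram` (pre-masking).
#' @param events a detected or ground-truth `EventTable`.
#' @param start_clock,lights_off_clock clock anchors.
#' @param transition_window_s see [assign_event_states()].
#' @return a nested list of class `"AnimalSummary"`.
#' @export
animal_summary <- function(hyp, events, start_clock = "07:00",
                           lights_off_clock = "19:00",
                           transition_window_s = 30) {
  events <- assign_event_states(events, hyp, transition_window_s)
  es <- event_summary(events)
  hc <- hourly_counts(events, start_clock)
  st <- state_totals(hyp, events, start_clock, lights_off_clock)
  props <- if (nrow(events)) state_event_proportions(events) else
    stats::setNames(rep(NA_real_, 3), SLEEP_STATES)
  n_nrem <- sum(events$onset_state == "NREM")
  out <- list(
    swd = c(es, list(
      hourly_counts = hc,
      phase_counts = phase_split(hc, lights_off_clock),
      onset_state_pct = props,
      transition_initiated = sum(events$transition_flag),
      transition_prop_all = if (es$count) mean(events$transition_flag) else NA_real_,
      transition_prop_nrem = if (n_nrem) sum(events$transition_flag) / n_nrem
                             else NA_real_)),
    states = st,
    events = events)
  class(out) <- "AnimalSummary"
  out
}

#' @export
print.AnimalSummary <- function(x, ...) {
  cat(sprintf("AnimalSummary: %d SWDs (total %.1f s), %.0f min recorded\n",
              x$swd$count, x$swd$total_duration_s, x$states$recording_min))
  tm <- vapply(SLEEP_STATES, function(s) x$states$total[[s]]$total_min, 0)
  cat("  minutes:", paste(sprintf("%s %.1f", SLEEP_STATES, tm), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy per-animal metric table for a cohort
#'
#' One row per animal with the headline 24-h metrics, suitable for export and
#' for group statistics.
#'
#' @param cohort list of animals from [make_cohort()], or any list with
#'   `group`, `animal`, `hypnogram`, `events` elements.
#' @param start_clock,lights_off_clock clock anchors.
#' @return data.frame with one row per animal.
#' @export
cohort_summary_table <- function(cohort, start_clock = "07:00",
                                 lights_off_clock = "19:00") {
  rows <- lapply(cohort, function(an) {
    s <- animal_summary(an$hypnogram, an$events, start_clock, lights_off_clock)
    data.frame(
      group = an$group, animal = an$animal,
      swd_count = s$swd$count,
      swd_mean_s = s$swd$mean_duration_s,
      swd_total_s = s$swd$total_duration_s,
      wake_min = s$states$total$WAKE$total_min,
      nrem_min = s$states$total$NREM$total_min,
      rem_min = s$states$total$REM$total_min,
      wake_bouts = s$states$total$WAKE$n_bouts,
      nrem_bouts = s$states$total$NREM$n_bouts,
      rem_bouts = s$states$total$REM$n_bouts,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare one metric between two groups of a cohort table
#'
#' @param tab a data.frame from [cohort_summary_table()].
#' @param metric column name to compare.
#' @param groups character vector of the two group labels (default: the two
#'   groups present, in order of appearance).
#' @param method passed to [two_sample_test()].
#' @return the [two_sample_test()] result plus group means.
#' @export
group_compare <- function(tab, metric, groups = unique(tab$group),
                          method = "welch_t") {
  if (length(groups) != 2) stop("need exactly two groups")
  a <- tab[[metric]][tab$group == groups[1]]
  b <- tab[[metric]][tab$group == groups[2]]
  res <- two_sample_test(a, b, method)
  res$mean_a <- mean(a); res$mean_b <- mean(b)
  res$groups <- groups; res$metric <- metric
  res
}
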