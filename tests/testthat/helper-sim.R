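# Shared fixtures, built in code. quick_sim() keeps unit tests on short
# recordings; the acceptance tests build their own full-scale inputs.

quick_sim <- function(duration_s = 600, seed = 42, ...) {
  simulate_recording(sim_config(duration_s = duration_s, seed = seed, ...))
}

# independent run-length oracle used for both bout segmentation and flag
# merging: naive index scan, no rle()
naive_runs <- function(x) {
  if (!length(x)) return(data.frame(value = character(), start = integer(),
                                    end = integer()))
  starts <- 1L; vals <- x[1]
  for (i in seq_along(x)[-1]) {
    if (!identical(x[i], x[i - 1])) {
      starts <- c(starts, i); vals <- c(vals, x[i])
    }
  }
  ends <- c(starts[-1] - 1L, length(x))
  data.frame(value = vals, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# naive flag merger: bridge short gaps, then collect runs, drop short events
naive_merge <- function(flags, epoch_len_s, merge_gap_s, min_event_s) {
  n <- length(flags)
  f <- as.logical(flags)
  runs <- naive_runs(f)
  for (i in seq_len(nrow(runs))) {
    if (!runs$value[i] && i > 1 && i < nrow(runs) &&
        (runs$end[i] - runs$start[i] + 1) * epoch_len_s <= merge_gap_s)
      f[runs$start[i]:runs$end[i]] <- TRUE
  }
  runs <- naive_runs(f)
  runs <- runs[runs$value & (runs$end - runs$start + 1) * epoch_len_s >=
                 min_event_s - 1e-9, , drop = FALSE]
  data.frame(start_s = (runs$start - 1) * epoch_len_s,
             end_s = runs$end * epoch_len_s)
}

# epochs of a hypnogram overlapped by any event, as a logical mask
event_epoch_mask <- function(hyp, events) {
  mask <- rep(FALSE, n_epochs(hyp))
  T <- hyp$epoch_len_s
  for (i in seq_len(nrow(events))) {
    k0 <- max(0, floor(events$start_s[i] / T))
    k1 <- min(n_epochs(hyp) - 1, ceiling(events$end_s[i] / T) - 1)
    if (k1 >= k0) mask[(k0:k1) + 1] <- TRUE
  }
  mask
}
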