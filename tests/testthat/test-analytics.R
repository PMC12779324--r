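test_that("bout segmentation equals the run-length oracle", {
  expect_equal(nrow(segment_bouts(hypnogram(rep("WAKE", 10), 5))), 1)
  h <- hypnogram(c("WAKE", "NREM", "WAKE", "NREM"), 5)
  b <- segment_bouts(h)
  expect_equal(nrow(b), 4)
  expect_true(all(b$duration_s == 5))
  set.seed(81)
  for (i in 1:1000) {
    lab <- sample(c("WAKE", "NREM", "REM"), sample(1:40, 1), replace = TRUE)
    b <- segment_bouts(hypnogram(lab, 5))
    o <- naive_runs(lab)
    expect_equal(b$state, o$value)
    expect_equal(b$start_epoch, o$start - 1L)
    expect_equal(b$end_epoch, o$end)
    # tiling invariant: bouts cover the hypnogram exactly, no equal neighbours
    expect_equal(sum(b$duration_s), length(lab) * 5)
    if (nrow(b) > 1) expect_true(all(b$state[-1] != b$state[-nrow(b)]))
  }
})

test_that("state totals: 24-h wake baseline, SWD masking arithmetic, conservation", {
  hyp <- hypnogram(rep("WAKE", 17280), 5)      # 24 h of 5-s epochs
  st <- state_totals(hyp)
  expect_equal(st$total$WAKE$total_min, 1440)
  expect_equal(st$total$WAKE$n_bouts, 1)
  expect_equal(sum(st$hourly_min["WAKE", ]), 1440)
  # one 60-s event masks 12 epochs out of wake
  ev <- event_table(100, 160)
  st2 <- state_totals(hyp, ev)
  expect_equal(st2$total$WAKE$total_min, 1440 - 1)
  expect_equal(st2$total$SWD$total_min, 1)
  # conservation under random hypnograms and events
  set.seed(82)
  for (i in 1:20) {
    lab <- sample(c("WAKE", "NREM", "REM", "UNSCORED"), 720, replace = TRUE)
    h <- hypnogram(lab, 5)
    ns <- sample(0:5, 1)
    if (ns > 0) {
      s0 <- sort(runif(ns, 0, 3500))
      e0 <- s0 + runif(ns, 1, 20)
      keep <- c(TRUE, s0[-1] > e0[-ns])
      evr <- event_table(s0[keep], pmin(e0[keep], 3600))
    } else evr <- event_table()
    sti <- state_totals(h, evr)
    tot <- sum(vapply(c("WAKE", "NREM", "REM", "SWD", "UNSCORED"),
                      function(s) sti$total[[s]]$total_min, 0))
    expect_equal(tot, sti$recording_min, tolerance = 1e-9)
    # hourly matrix sums to the same total
    expect_equal(sum(sti$hourly_min), sti$recording_min, tolerance = 1e-9)
    # light + dark = total
    expect_equal(sti$light$WAKE$total_min + sti$dark$WAKE$total_min,
                 sti$total$WAKE$total_min, tolerance = 1e-9)
  }
})

test_that("event-state assignment flags wake-to-NREM transition SWDs", {
  # WAKE bout then NREM bout; SWD 2 s into the NREM bout -> flagged
  lab <- c(rep("WAKE", 12), rep("NREM", 60))
  hyp <- hypnogram(lab, 5)
  ev <- assign_event_states(event_table(62, 65), hyp)
  expect_equal(ev$onset_state, "NREM")
  expect_true(ev$transition_flag)
  # SWD late in the NREM bout (beyond the 30-s window) -> not flagged
  ev2 <- assign_event_states(event_table(200, 204), hyp)
  expect_equal(ev2$onset_state, "NREM")
  expect_false(ev2$transition_flag)
  # SWD in the middle of a long wake bout -> onset WAKE, no flag
  lab3 <- rep("WAKE", 120)
  ev3 <- assign_event_states(event_table(300, 304), hypnogram(lab3, 5))
  expect_equal(ev3$onset_state, "WAKE")
  expect_false(ev3$transition_flag)
  # NREM bout preceded by REM (not WAKE): no flag even near bout start
  lab4 <- c(rep("NREM", 12), rep("REM", 12), rep("NREM", 24))
  ev4 <- assign_event_states(event_table(121, 124), hypnogram(lab4, 5))
  expect_false(ev4$transition_flag)
  expect_error(assign_event_states(event_table(1e5, 1e5 + 1), hyp),
               "beyond hypnogram")
})

test_that("batch event-state assignment equals per-event lookup and batch splitting", {
  set.seed(83)
  lab <- sample(c("WAKE", "NREM", "REM"), 720, replace = TRUE)
  hyp <- hypnogram(lab, 5)
  s0 <- sort(runif(30, 0, 3500)); e0 <- s0 + 1
  keep <- c(TRUE, s0[-1] > e0[-30] + 0.1)
  ev <- event_table(s0[keep], e0[keep])
  full <- assign_event_states(ev, hyp)
  # per-event brute-force lookup
  for (i in seq_len(nrow(full))) {
    single <- assign_event_states(ev[i, , drop = FALSE], hyp)
    expect_equal(full$onset_state[i], single$onset_state)
    expect_equal(full$transition_flag[i], single$transition_flag)
    expect_equal(full$onset_state[i],
                 lab[floor(full$start_s[i] / 5) + 1])
  }
})

test_that("onset-state proportions and their generator-level sampling check", {
  ev <- event_table(seq(0, 190, by = 10), seq(2, 192, by = 10),
                    onset_state = c(rep("WAKE", 19), "NREM"))
  p <- state_event_proportions(ev)
  expect_equal(unname(p), c(95, 5, 0))
  ev_rem <- event_table(c(0, 10), c(1, 11), onset_state = c("REM", "REM"))
  expect_equal(unname(state_event_proportions(ev_rem)), c(0, 0, 100))
  expect_error(state_event_proportions(event_table()), "empty")
  # generator default preference: 1,000 events land within 2 points of the
  # configured (94.8, 4.4, 0.5)% onset-state split
  cfg <- sim_config(duration_s = 86400, swd_n_events = 1000,
                    swd_min_gap_s = 1, swd_duration_s = c(2, 0.3),
                    seed = 84)
  sim <- simulate_recording(cfg, signals = FALSE)
  pr <- state_event_proportions(sim$events)
  expect_lt(abs(pr[["WAKE"]] - 94.8), 2)
  expect_lt(abs(pr[["NREM"]] - 4.4), 2)
  expect_lt(abs(pr[["REM"]] - 0.5), 2)
})

test_that("hourly bins and phase split follow clock anchoring conventions", {
  # onset exactly on an hour boundary goes to the later bin
  ev <- event_table(3600, 3605)          # one hour after a 07:00 start
  hc <- hourly_counts(ev, "07:00")
  expect_equal(unname(hc["h08"]), 1L)
  expect_equal(sum(hc), 1L)
  expect_true(all(hourly_counts(event_table()) == 0))
  set.seed(85)
  s0 <- sort(runif(40, 0, 86390)); ev2 <- event_table(s0, s0 + 0.5)
  expect_equal(sum(hourly_counts(ev2)), 40L)
  ph <- phase_split(hourly_counts(ev2, "07:00"), "19:00")
  expect_equal(unname(ph["light"] + ph["dark"]), 40)
  # dark phase covers 19:00-07:00
  hv <- setNames(rep(0, 24), sprintf("h%02d", 0:23)); hv["h20"] <- 3
  expect_equal(unname(phase_split(hv, "19:00")["dark"]), 3)
})

test_that("percent-of-baseline normalisation guards a zero baseline", {
  expect_equal(percent_of_baseline(12, 12), 100)
  expect_equal(percent_of_baseline(5, 20), 25)
  expect_error(percent_of_baseline(5, 0), "baseline")
})

test_that("animal summaries assemble consistent per-animal metrics", {
  cfg <- sim_config(duration_s = 21600, swd_n_events = 30, seed = 86)
  sim <- simulate_recording(cfg, signals = FALSE)
  s <- animal_summary(sim$hypnogram, sim$events)
  expect_equal(s$swd$count, 30)
  expect_equal(sum(s$swd$hourly_counts), 30)
  expect_equal(unname(sum(s$swd$phase_counts)), 30)
  tot <- sum(vapply(c("WAKE", "NREM", "REM", "SWD", "UNSCORED"),
                    function(x) s$states$total[[x]]$total_min, 0))
  expect_equal(tot, 360, tolerance = 1e-9)
  expect_equal(sum(s$swd$onset_state_pct), 100, tolerance = 1e-9)
})
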