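test_that("generator is deterministic and honours degenerate configs", {
  cfg <- sim_config(duration_s = 300, seed = 123)
  s1 <- simulate_recording(cfg)
  s2 <- simulate_recording(cfg)
  expect_identical(s1$hypnogram$labels, s2$hypnogram$labels)
  expect_identical(s1$recording$signals, s2$recording$signals)
  expect_identical(as.data.frame(s1$events), as.data.frame(s2$events))
  # absorbing chain: identity transition matrix keeps the initial state
  cfg_id <- sim_config(duration_s = 600, seed = 1,
                       state_transition_matrix = diag(3))
  hyp <- generate_hypnogram(cfg_id, init_state = "WAKE")
  expect_true(all(hyp$labels == "WAKE"))
  # zero-duration recording: empty, no error
  cfg0 <- sim_config(duration_s = 0, seed = 1)
  hyp0 <- generate_hypnogram(cfg0)
  expect_equal(n_epochs(hyp0), 0)
  rec0 <- synthesize_signals(hyp0, cfg0)
  expect_equal(ncol(rec0$signals), 0)
})

test_that("invalid configurations are rejected with configuration errors", {
  expect_error(sim_config(state_transition_matrix = matrix(1, 3, 3)),
               "rows summing to 1")
  bad <- default_transition_matrix(); bad[1, 3] <- bad[1, 2]; bad[1, 2] <- 0
  expect_error(sim_config(state_transition_matrix = bad), "WAKE -> REM")
  expect_error(sim_config(swd_f0_hz = 12), "\\[5, 10\\]")
  expect_error(sim_config(swd_state_preference = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(sim_config(fs = 60), "twice the highest band edge")
})

test_that("24-h state fractions match the chain's stationary distribution (eigen oracle)", {
  # homogeneous chain (no dark bias) against its eigen stationary vector
  cfg <- sim_config(seed = 7, dark_phase_wake_bias = 1)
  hyp <- generate_hypnogram(cfg)
  P <- cfg$state_transition_matrix
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  pi_oracle <- v / sum(v)
  emp <- as.numeric(table(factor(hyp$labels, levels = c("WAKE", "NREM", "REM")))) /
    n_epochs(hyp)
  expect_true(all(abs(emp - pi_oracle) < 0.03))
})

test_that("state signatures: EMG atonia in REM, band-power ordering per state", {
  cfg <- sim_config(duration_s = 1800, seed = 11, swd_rate_per_h = 0)
  sim <- simulate_recording(cfg)
  spe <- round(cfg$epoch_len_s * cfg$fs)
  emg <- get_channel(sim$recording, role = "EMG")
  nep <- n_epochs(sim$hypnogram)
  er <- sqrt(colMeans(matrix(emg[1:(nep * spe)], spe)^2))
  lab <- sim$hypnogram$labels
  if (any(lab == "REM") && any(lab == "WAKE")) {
    expect_lt(max(er[lab == "REM"]), 0.5 * min(er[lab == "WAKE"]))
  }
  bp <- epoch_band_powers(sim$recording)
  expect_true(all(bp[lab == "NREM", "delta"] > bp[lab == "NREM", "theta"]))
  expect_true(all(bp[lab == "REM", "theta"] > bp[lab == "REM", "delta"]))
})

test_that("SWD injection: counts, null injection, spectral content, placement bound", {
  cfg <- sim_config(duration_s = 3600, swd_n_events = 10, seed = 21)
  sim <- simulate_recording(cfg)
  expect_equal(nrow(sim$events), 10)
  validate_events(sim$events)
  expect_true(all(diff(sim$events$start_s) > 0))
  # zero rate: recording untouched
  cfg0 <- sim_config(duration_s = 600, swd_rate_per_h = 0, seed = 22)
  hyp <- generate_hypnogram(cfg0)
  rec <- synthesize_signals(hyp, cfg0)
  inj <- inject_swd_events(rec, hyp, cfg0)
  expect_equal(nrow(inj$events), 0)
  expect_identical(inj$recording$signals, rec$signals)
  # injected 7 Hz event: PSD global max in 5-10 Hz, local max at 14 +/- 1 Hz
  cfg7 <- sim_config(duration_s = 1200, swd_n_events = 6, swd_f0_hz = 7,
                     seed = 23)
  sim7 <- simulate_recording(cfg7)
  ev <- sim7$events[1, ]
  fs <- cfg7$fs
  seg <- get_channel(sim7$recording)[
    floor(ev$start_s * fs):ceiling(ev$end_s * fs)]
  psd <- welch_psd(seg, fs, window_s = 1)
  fmax <- psd$freqs[which.max(psd$power)]
  expect_gte(fmax, 5); expect_lte(fmax, 10)
  p <- psd$power
  locmax <- which(c(FALSE, p[-c(1, length(p))] > p[-c(length(p) - 1, length(p))] &
                      p[-c(1, length(p))] >= p[-(1:2)], FALSE))
  expect_true(any(abs(psd$freqs[locmax] - 14) <= 1))
  # impossible rate errors out after bounded retries
  cfg_hi <- sim_config(duration_s = 120, swd_n_events = 200, seed = 24)
  hyp_hi <- generate_hypnogram(cfg_hi)
  rec_hi <- synthesize_signals(hyp_hi, cfg_hi)
  expect_error(inject_swd_events(rec_hi, hyp_hi, cfg_hi), "placement failed")
})

test_that("cohorts: sizes, distinct deterministic seeds, effect-multiplier behaviour", {
  specs <- list(list(label = "wt", n = 9),
                list(label = "het", n = 15))
  coh <- make_cohort(specs, cfg = sim_config(duration_s = 600), seed = 31,
                     signals = FALSE)
  expect_length(coh, 24)
  seeds <- vapply(coh, function(a) a$config$seed, 0L)
  expect_equal(length(unique(seeds)), 24)
  # seeds are stable under group-size changes elsewhere
  coh2 <- make_cohort(list(list(label = "wt", n = 2),
                           list(label = "het", n = 15)),
                      cfg = sim_config(duration_s = 600), seed = 31,
                      signals = FALSE)
  expect_equal(coh2[[3]]$config$seed, coh[[10]]$config$seed)
  expect_error(make_cohort(list()), "empty group_specs")
})

test_that("null-multiplier groups are statistically exchangeable", {
  nonsig <- vapply(1:50, function(r) {
    coh <- make_cohort(list(list(label = "a", n = 9),
                            list(label = "b", n = 15)),
                       cfg = sim_config(duration_s = 10800),
                       seed = mix_seed(500, r), signals = FALSE)
    tab <- cohort_summary_table(coh)
    group_compare(tab, "rem_min")$p >= 0.05
  }, TRUE)
  expect_gte(mean(nonsig), 0.9)
})

test_that("a tenfold SWD-rate multiplier dominates the control group in every replicate", {
  higher <- vapply(1:20, function(r) {
    coh <- make_cohort(list(list(label = "ctl", n = 4),
                            list(label = "mut", n = 4, rate_multiplier = 10)),
                       cfg = sim_config(duration_s = 7200),
                       seed = mix_seed(900, r), signals = FALSE)
    tab <- cohort_summary_table(coh)
    mean(tab$swd_count[tab$group == "mut"]) >
      mean(tab$swd_count[tab$group == "ctl"])
  }, TRUE)
  expect_true(all(higher))
})
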