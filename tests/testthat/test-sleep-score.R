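fake_features <- function(delta, theta, emg) {
  df <- data.frame(delta_power = delta, theta_power = theta,
                   total_power = delta + theta,
                   theta_delta_ratio = theta / delta,
                   emg_rms = emg, degenerate = FALSE)
  class(df) <- c("EpochFeatures", "data.frame")
  df
}

test_that("feature extraction: epoch counts, degenerate flag, REM theta dominance", {
  cfg <- sim_config(duration_s = 60, swd_rate_per_h = 0, seed = 71)
  sim <- simulate_recording(cfg)
  f <- extract_features(sim$recording)
  expect_equal(nrow(f), 12)                 # 60 s at 5-s epochs
  # zero signal -> degenerate
  z <- recording(matrix(0, 2, 250.4 * 20), 250.4, c("e", "m"), c("EEG", "EMG"))
  fz <- extract_features(z)
  expect_true(all(fz$degenerate))
  expect_error(classify_epochs(fz), "degenerate")
  # REM epochs are theta-dominant
  cfg_rem <- sim_config(duration_s = 300, swd_rate_per_h = 0, seed = 72,
                        state_transition_matrix = rbind(c(0, 1, 0),
                                                        c(0, 0, 1),
                                                        c(0, 0, 1)))
  hyp <- generate_hypnogram(cfg_rem, init_state = "REM")
  rec <- synthesize_signals(hyp, cfg_rem)
  fr <- extract_features(rec)
  rem_rows <- hyp$labels[seq_len(nrow(fr))] == "REM"
  expect_gte(mean(fr$theta_delta_ratio[rem_rows] > 1), 0.9)
})

test_that("classification rules fire in cascade order", {
  # epochs above the EMG percentile are wake regardless of spectrum
  f <- fake_features(delta = rep(c(10, 1), 10), theta = rep(1, 20),
                     emg = c(rep(1, 12), rep(30, 8)))
  lab <- classify_epochs(f, scorer_config(emg_wake_percentile = 60))
  expect_true(all(lab[13:20] == "WAKE"))
  expect_false(any(lab[1:12] == "WAKE"))
  # among low-EMG epochs: high delta -> NREM; low delta + high ratio -> REM
  f2 <- fake_features(delta = c(rep(10, 10), rep(1, 10)),
                      theta = c(rep(1, 10), rep(3, 10)),
                      emg = rep(0.01, 20))
  lab2 <- classify_epochs(f2, scorer_config(emg_wake_percentile = 99,
                                            delta_nrem_percentile = 50))
  expect_true(all(lab2[1:10] == "NREM"))
  expect_true(all(lab2[11:20] == "REM"))
})

test_that("smoothing absorbs short bouts, forbids wake-to-REM, and is idempotent", {
  cfg <- scorer_config(smoothing_min_bout_epochs = 2)
  expect_equal(smooth_hypnogram(c("WAKE", "WAKE", "REM", "WAKE", "WAKE"),
                                cfg)$labels, rep("WAKE", 5))
  keep <- c("NREM", "NREM", "REM", "REM", "REM", "NREM")
  expect_equal(smooth_hypnogram(keep, cfg)$labels, keep)
  # wake-to-REM: first REM epoch after wake becomes NREM
  wr <- c("WAKE", "WAKE", "WAKE", "REM", "REM", "REM", "REM")
  sm <- smooth_hypnogram(wr, cfg)$labels
  expect_false(any(sm[-1] == "REM" & sm[-length(sm)] == "WAKE"))
  set.seed(73)
  for (i in 1:50) {
    lab <- sample(c("WAKE", "NREM", "REM"), 40, replace = TRUE)
    once <- smooth_hypnogram(lab, cfg)$labels
    twice <- smooth_hypnogram(once, cfg)$labels
    expect_identical(twice, once)
    # no label invented beyond the forbid-wake-to-REM relabeling
    expect_true(all(unique(once) %in% unique(c(lab, "NREM"))))
  }
})

test_that("full scorer: accuracy before and after smoothing, determinism, scale invariance", {
  cfg <- sim_config(duration_s = 7200, swd_rate_per_h = 0, seed = 74)
  sim <- simulate_recording(cfg)
  feats <- extract_features(sim$recording)
  raw <- classify_epochs(feats)
  truth <- sim$hypnogram$labels[seq_along(raw)]
  expect_gte(mean(raw == truth), 0.85)      # raw cascade, no smoothing
  hyp1 <- score_sleep(sim$recording)
  v <- validate_against(hyp1, sim$hypnogram)
  expect_gte(v$global_agreement_pct, 90)
  hyp2 <- score_sleep(sim$recording)
  expect_identical(hyp2$labels, hyp1$labels)
  rec_scaled <- sim$recording
  rec_scaled$signals <- rec_scaled$signals * 7.5
  expect_identical(score_sleep(rec_scaled)$labels, hyp1$labels)
})

test_that("an all-wake recording scores all wake", {
  cfg <- sim_config(duration_s = 600, swd_rate_per_h = 0, seed = 75,
                    state_transition_matrix = diag(3))
  hyp <- generate_hypnogram(cfg, init_state = "WAKE")
  rec <- synthesize_signals(hyp, cfg)
  scored <- score_sleep(rec)
  expect_true(all(scored$labels == "WAKE"))
  # and an all-NREM recording scores all NREM
  hyp_n <- generate_hypnogram(sim_config(duration_s = 600, swd_rate_per_h = 0,
                                         seed = 76,
                                         state_transition_matrix = diag(3)),
                              init_state = "NREM")
  rec_n <- synthesize_signals(hyp_n, sim_config(duration_s = 600, seed = 76))
  expect_true(all(score_sleep(rec_n)$labels == "NREM"))
})

test_that("scorer validation reproduces counting and formula oracles", {
  a <- hypnogram(c("WAKE", "NREM", "REM", "NREM"), 5)
  v <- validate_against(a, a)
  expect_equal(v$global_agreement_pct, 100)
  expect_equal(v$kappa, 1)
  ref <- hypnogram(rep("NREM", 10), 5)
  auto <- hypnogram(rep("WAKE", 10), 5)
  v2 <- validate_against(auto, ref)
  expect_equal(unname(v2$per_state_agreement_pct["NREM"]), 0)
  expect_equal(v2$kappa, 0)
  set.seed(76)
  labs <- c("WAKE", "NREM", "REM")
  for (i in 1:20) {
    r <- hypnogram(sample(labs, 60, TRUE), 5)
    u <- hypnogram(sample(labs, 60, TRUE), 5)
    v3 <- validate_against(u, r)
    # brute-force per-epoch tally
    acc <- mean(u$labels == r$labels)
    expect_equal(v3$global_agreement_pct, 100 * acc, tolerance = 1e-9)
    for (st in labs) {
      sel <- r$labels == st
      expect_equal(unname(v3$per_state_agreement_pct[st]),
                   100 * mean(u$labels[sel] == st), tolerance = 1e-9)
    }
  }
  expect_error(validate_against(a, hypnogram(rep("WAKE", 3), 5)),
               "different epoch grids")
})
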