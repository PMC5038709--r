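# Synthetic cohort generator: Markov trajectories, signal ground truth,
# scale scores, determinism and class balance.

test_that("state trajectories follow the transition matrix", {
  idm <- diag(3); dimnames(idm) <- list(c("N", "A", "E"), c("N", "A", "E"))
  expect_equal(sample_state_trajectory(idm, 10, "N", seed = 1),
               rep("N", 10))
  absorb <- matrix(c(0.5, 0.5, 0, 0, 0.5, 0.5, 0, 0, 1), 3, byrow = TRUE,
                   dimnames = list(c("N", "A", "E"), c("N", "A", "E")))
  expect_equal(sample_state_trajectory(absorb, 8, "E", seed = 2),
               rep("E", 8))
  # law of large numbers against the exact uniform stationary distribution
  q <- sample_state_trajectory(uniform3(), 100000, "N", seed = 3)
  expect_true(all(abs(table(q) / length(q) - 1 / 3) < 0.01))
})

test_that("invalid transition matrices and configs are rejected", {
  bad <- matrix(c(0.9, 0.2, 0, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_error(sample_state_trajectory(bad, 5, "N"), "sum to 1")
  expect_error(cohort_config(n_subjects = 10,
                             class_counts = c(E = 1, A = 1, N = 1)),
               "sum to n_subjects")
  expect_error(synthesize_ecg("N", 10, fs = 50), "100 Hz")
})

test_that("ECG beats are placed exactly at the configured rate", {
  eff <- default_state_effects()
  eff$N$hr_bpm <- 60; eff$N$rr_jitter_sd <- 0
  ecg <- synthesize_ecg("N", 10, 250, eff, seed = 1, noise_sd = 0)
  expect_length(ecg$beats, 10)
  expect_equal(diff(ecg$beats), rep(1, 9), tolerance = 1e-12)
  # state E raises the rate by the configured offset
  eff$E$rr_jitter_sd <- 0
  ecgE <- synthesize_ecg("E", 30, 250, eff, seed = 2, noise_sd = 0)
  expect_equal(mean(diff(ecgE$beats)), 60 / default_state_effects()$E$hr_bpm,
               tolerance = 0.02)
})

test_that("EDA ground truth matches injected and Poisson schedules", {
  eff <- default_state_effects()
  ev <- data.frame(time = c(5, 20, 30, 40, 50), amplitude = rep(0.5, 5))
  eda <- synthesize_eda("N", 60, 16, eff, seed = 1, noise_sd = 0,
                        events = ev)
  expect_equal(nrow(eda$scr_events), 5)
  eff0 <- eff; eff0$N$scr_rate_per_min <- 0
  quiet <- synthesize_eda("N", 60, 16, eff0, seed = 1, noise_sd = 0)
  expect_equal(nrow(quiet$scr_events), 0)
  expect_lt(max(abs(quiet$samples - mean(quiet$samples))), 0.25)
  eff0$N$scr_rate_per_min <- -1
  expect_error(synthesize_eda("N", 10, 16, eff0), "negative")
  # doubled SCR rate doubles the mean Poisson event count
  effd <- eff; effd$N$scr_rate_per_min <- 3; effd$E$scr_rate_per_min <- 6
  nE <- mean(sapply(1:10, function(i)
    nrow(synthesize_eda("E", 300, 16, effd, seed = 100 + i)$scr_events)))
  nN <- mean(sapply(1:10, function(i)
    nrow(synthesize_eda("N", 300, 16, effd, seed = 200 + i)$scr_events)))
  expect_equal(nE / nN, 2, tolerance = 0.2)
})

test_that("BVP pulses ride the ECG beat schedule", {
  eff <- default_state_effects()
  eff$N$hr_bpm <- 60; eff$N$rr_jitter_sd <- 0
  bvp <- synthesize_bvp("N", 20, 64, eff, seed = 1, noise_sd = 0)
  expect_equal(diff(bvp$fiducials$m_time), rep(1, nrow(bvp$fiducials) - 1),
               tolerance = 1e-9)
  expect_equal(bvp$fiducials$dia_amp / bvp$fiducials$sys_amp,
               rep(eff$N$bvp_dia_ratio, nrow(bvp$fiducials)))
  beats <- synthesize_ecg("N", 20, 250, eff, seed = 3, noise_sd = 0)$beats
  locked <- synthesize_bvp("N", 20, 64, eff, seed = 4, beats = beats)
  expect_equal(locked$fiducials$beat, beats)
})

test_that("EMG gap schedule is honored and zero burst leaves rest-level RMS", {
  eff <- default_state_effects()
  g <- data.frame(start = c(10, 25, 40, 50), duration = rep(1, 4))
  emg <- synthesize_emg("N", 60, 500, eff, seed = 1, gaps = g)
  expect_equal(nrow(emg$gaps), 4)
  eff0 <- eff; eff0$N$emg_burst_amp <- 0
  flat <- synthesize_emg("N", 30, 500, eff0, seed = 2,
                         gaps = data.frame(start = numeric(0),
                                           duration = numeric(0)))
  rest_rms <- sqrt(mean(flat$samples^2))
  # envelope is the rest level everywhere; carrier variance is slightly
  # below 1 after band-limiting
  expect_lt(rest_rms, flat$rest_amp * 1.1)
  expect_gt(rest_rms, flat$rest_amp * 0.5)
})

test_that("scale scores respect ranges and the item-3 state mapping", {
  cfg <- cohort_config()
  szero <- cfg
  szero$scale_score_means$BDI$E["sd"] <- 0
  szero$scale_score_means$BDI$E["mean"] <- 40
  s <- sample_scale_scores("E", szero, seed = 1)
  expect_equal(s[["BDI"]], 40L)
  rng <- sapply(1:50, function(i) sample_scale_scores("E", cfg, seed = i)[["BDI"]])
  expect_true(all(rng >= 0 & rng <= 63))
  hrsd_n <- sapply(1:20, function(i) sample_scale_scores("N", cfg, seed = i)[["HRSD3"]])
  hrsd_a <- sapply(1:20, function(i) sample_scale_scores("A", cfg, seed = i)[["HRSD3"]])
  hrsd_e <- sapply(1:20, function(i) sample_scale_scores("E", cfg, seed = i)[["HRSD3"]])
  expect_true(all(hrsd_n == 0))
  expect_true(all(hrsd_a %in% 1:2))
  expect_true(all(hrsd_e %in% 3:4))
})

test_that("cohort generation is deterministic with the configured balance", {
  cfg <- tiny_cohort_config(seed = 11, n_subjects = 5,
                            class_counts = c(E = 2, A = 1, N = 2))
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1, coh2)
  dom <- sapply(coh1, `[[`, "dominant")
  expect_equal(sum(dom == "E"), 2)
  expect_equal(sum(dom == "N"), 2)
  for (rec in coh1) {
    n_slots <- length(rec$true_states)
    expect_equal(n_slots, cfg$window_w)
    expect_gte(mean(rec$true_states == rec$dominant), cfg$dominant_floor)
    for (ch in names(rec$channels))
      expect_equal(length(rec$channels[[ch]]),
                   round(n_slots * cfg$tau_seconds * cfg$fs_per_sensor[[ch]]))
  }
})

test_that("cohort survives its on-disk round trip", {
  cfg <- tiny_cohort_config(seed = 3, n_subjects = 2,
                            class_counts = c(E = 1, A = 0, N = 1))
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$true_states, coh[[1]]$true_states)
  expect_equal(back[[1]]$scale_scores, coh[[1]]$scale_scores)
  expect_equal(back[[2]]$channels$ecg, coh[[2]]$channels$ecg,
               tolerance = 1e-12)
  expect_equal(back[[1]]$dominant, coh[[1]]$dominant)
})
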