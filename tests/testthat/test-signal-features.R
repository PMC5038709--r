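# Preprocessing and per-sensor feature extraction, validated against the
# generators' ground truth on noise-free settings.

test_that("band-pass filter keeps the pass band and kills the stop band", {
  fs <- 250
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  stop_tone <- sin(2 * pi * 50 * t)
  pass_tone <- sin(2 * pi * 10 * t)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(bandpass_filter(stop_tone, fs, 0.5, 40)),
            0.05 * rms(stop_tone))
  expect_equal(rms(bandpass_filter(pass_tone, fs, 0.5, 40)),
               rms(pass_tone), tolerance = 0.05)
  dc <- pass_tone + 3
  expect_lt(abs(mean(bandpass_filter(dc, fs, 0.5, 40))), 0.01 * 3)
  # filtering twice barely changes pass-band content
  once <- bandpass_filter(pass_tone, fs, 0.5, 40)
  twice <- bandpass_filter(once, fs, 0.5, 40)
  expect_equal(rms(twice), rms(once), tolerance = 0.01)
  expect_error(bandpass_filter(pass_tone, fs, 40, 0.5), "band edges")
  expect_error(bandpass_filter(pass_tone, fs, 10, 200), "band edges")
})

test_that("trailing moving average matches its arithmetic definition", {
  expect_equal(moving_average(rep(4.2, 50), 15), rep(4.2, 50))
  x <- rnorm(20)
  expect_equal(moving_average(x, 1), x)
  y <- moving_average(as.numeric(1:30), 15)
  expect_equal(y[15], mean(1:15))
  expect_equal(y[1], 1)
  expect_equal(y[7], mean(1:7))  # truncated edge window
  expect_error(moving_average(1:5, 6), "window")
})

test_that("R-peak detection recovers generator beats within one sample", {
  eff <- default_state_effects()
  eff$N$hr_bpm <- 60; eff$N$rr_jitter_sd <- 0
  ecg <- synthesize_ecg("N", 10, 250, eff, seed = 1, noise_sd = 0)
  pk <- detect_r_peaks(ecg$samples, 250)
  expect_length(pk, 10)
  expect_true(all(abs((pk - 1) / 250 - ecg$beats) <= 1 / 250))
  expect_identical(detect_r_peaks(numeric(2500), 250), integer(0))
  # two template beats 0.5 s apart at 250 Hz
  two <- synthesize_ecg("N", 2, 250,
                        within_effects(eff, "N", hr_bpm = 120,
                                       rr_jitter_sd = 0),
                        seed = 2, noise_sd = 0)
  pk2 <- detect_r_peaks(two$samples, 250)
  expect_true(all(abs(diff(pk2) - 125) <= 1))
  # jittered noisy beats still recovered within 2 sample periods
  ecgj <- synthesize_ecg("A", 20, 250, default_state_effects(), seed = 3,
                         noise_sd = 0.02)
  pkj <- detect_r_peaks(bandpass_filter(ecgj$samples, 250, 0.5, 40), 250)
  expect_equal(length(pkj), length(ecgj$beats))
  expect_true(all(abs((pkj - 1) / 250 - ecgj$beats) <= 2 / 250))
})

test_that("ECG slot features and QTc arithmetic are correct", {
  expect_equal(qtc_bazett(0.40, 1.0), 0.40)
  expect_equal(qtc_bazett(0.36, 0.81), 0.40)
  eff <- default_state_effects()
  eff$N$hr_bpm <- 60; eff$N$rr_jitter_sd <- 0
  ecg <- synthesize_ecg("N", 20, 250, eff, seed = 1, noise_sd = 0)
  f <- ecg_features(ecg$samples, 250)
  expect_equal(f[["ecg_rr_mean"]], 1, tolerance = 0.005)
  expect_equal(f[["ecg_rr_var"]], 0, tolerance = 1e-6)
  expect_equal(f[["ecg_rr_d1"]], 0, tolerance = 1e-6)
  expect_equal(f[["ecg_hr_bpm"]], 60, tolerance = 0.5)
  expect_equal(f[["ecg_qtc"]], f[["ecg_qt"]], tolerance = 0.01)
  # too few beats -> flagged missing, not zeros
  short <- ecg_features(ecg$samples[1:200], 250)
  expect_true(all(is.na(short)))
  # E-state heart-rate offset is recovered from detected intervals
  effE <- default_state_effects(); effE$E$rr_jitter_sd <- 0.01
  ecgE <- synthesize_ecg("E", 30, 250, effE, seed = 5, noise_sd = 0)
  fE <- ecg_features(ecgE$samples, 250)
  expect_equal(fE[["ecg_rr_mean"]], 60 / effE$E$hr_bpm, tolerance = 0.02)
})

test_that("EDA slot features recover injected SCR ground truth", {
  eff <- default_state_effects()
  ev <- data.frame(time = c(5, 17, 29, 41, 53), amplitude = rep(0.5, 5))
  eda <- synthesize_eda("N", 60, 16, eff, seed = 1, noise_sd = 0,
                        events = ev)
  f <- eda_features(bandpass_filter(eda$samples, 16, 0, 1), 16)
  expect_equal(f[["eda_scr_count"]], 5)
  expect_equal(f[["eda_scr_freq"]], 5)
  expect_equal(f[["eda_scr_amp"]], 0.5, tolerance = 0.1)
  expect_equal(f[["eda_scl_mean"]], mean(eda$samples), tolerance = 1e-3)
  ev2 <- data.frame(time = c(10, 40), amplitude = c(0.2, 0.4))
  eda2 <- synthesize_eda("N", 60, 16, eff, seed = 2, noise_sd = 0,
                         events = ev2)
  f2 <- eda_features(bandpass_filter(eda2$samples, 16, 0, 1), 16)
  expect_equal(f2[["eda_scr_amp"]], 0.3, tolerance = 0.1)
  # tonic-only signal: level recovered, no events
  eff0 <- eff; eff0$N$scr_rate_per_min <- 0; eff0$N$scl_tonic <- 2.0
  eda3 <- synthesize_eda("N", 60, 16, eff0, seed = 3, noise_sd = 0.01)
  f3 <- eda_features(bandpass_filter(eda3$samples, 16, 0, 1), 16)
  expect_equal(f3[["eda_scr_count"]], 0)
  expect_equal(f3[["eda_scl_mean"]], 2.0, tolerance = 0.1)
  expect_true(is.na(f3[["eda_scr_amp"]]))
})

test_that("BVP slot features recover the pulse template parameters", {
  eff <- default_state_effects()
  eff$N$hr_bpm <- 60; eff$N$rr_jitter_sd <- 0
  eff$N$bvp_dia_ratio <- 0.5
  bvp <- synthesize_bvp("N", 30, 64, eff, seed = 1, noise_sd = 0)
  f <- bvp_features(bvp$samples, 64)
  expect_equal(f[["bvp_mm_mean"]], 1, tolerance = 0.01)
  expect_lt(f[["bvp_mm_sd"]], 0.02)
  expect_equal(f[["bvp_aug_idx"]], 0.5, tolerance = 0.05)
  expect_equal(f[["bvp_mq_mean"]], 0.3, tolerance = 0.05)
  expect_equal(f[["bvp_pulse_interval"]], 1, tolerance = 0.02)
  # zero diastolic component -> Q-dependent features flagged missing
  eff0 <- eff; eff0$N$bvp_dia_ratio <- 0
  bvp0 <- synthesize_bvp("N", 30, 64, eff0, seed = 2, noise_sd = 0)
  f0 <- bvp_features(bvp0$samples, 64)
  expect_true(is.na(f0[["bvp_mq_mean"]]))
  expect_true(is.na(f0[["bvp_aug_idx"]]))
  expect_false(is.na(f0[["bvp_sys_amp"]]))
})

test_that("EMG slot features match spectrum and gap schedule", {
  eff <- default_state_effects()
  # flat 20-200 Hz band: median frequency near the band midpoint
  set.seed(42)
  fs <- 1000
  x <- bandpass_filter(rnorm(60 * fs), fs, 20, 200)
  f <- emg_features(x, fs)
  expect_equal(f[["emg_median_freq"]], 110, tolerance = 0.1 * 110)
  g <- data.frame(start = c(10, 25, 40, 50), duration = rep(1, 4))
  emg <- synthesize_emg("N", 60, 500, eff, seed = 1, gaps = g)
  fg <- emg_features(emg$samples, 500)
  expect_equal(fg[["emg_gaps_per_min"]], 4)
  expect_equal(fg[["emg_gap_pct"]], 4 / 60 * 100, tolerance = 1.5)
  # envelope never below threshold -> zero gap time
  none <- synthesize_emg("N", 30, 500, eff, seed = 2,
                         gaps = data.frame(start = numeric(0),
                                           duration = numeric(0)))
  fn <- emg_features(none$samples, 500)
  expect_equal(fn[["emg_gaps_per_min"]], 0)
  expect_equal(fn[["emg_gap_pct"]], 0)
})

test_that("fused feature vectors carry groups, encodings and missingness", {
  cfg <- tiny_cohort_config(seed = 5, n_subjects = 1,
                            class_counts = c(E = 1, A = 0, N = 0))
  rec <- generate_cohort(cfg)[[1]]
  fv <- build_feature_vector(rec, 3)
  expect_s3_class(fv, "feature_vector")
  expect_true(all(c("ECG", "EDA", "BVP", "EMG") %in% fv$groups))
  expect_false(any(duplicated(names(fv$values))))
  expect_equal(fv$values[["family_suicide_history"]],
               as.numeric(rec$history[["family_suicide_history"]]))
  expect_false("HRSD3" %in% names(fv$values))
  # missing EMG channel: EMG features flagged, others intact
  rec2 <- rec
  rec2$channels$emg <- NULL
  fv2 <- build_feature_vector(rec2, 3)
  expect_true(all(is.na(fv2$values[fv2$groups == "EMG"])))
  expect_equal(fv2$values[fv2$groups == "ECG"], fv$values[fv$groups == "ECG"])
})

test_that("feature extraction is slot-local", {
  cfg <- tiny_cohort_config(seed = 9, n_subjects = 1,
                            class_counts = c(E = 0, A = 0, N = 1))
  rec <- generate_cohort(cfg)[[1]]
  fv_before <- build_feature_vector(rec, 4)
  rec2 <- rec
  # vandalize every sample outside slot 4
  for (ch in names(rec2$channels)) {
    fs <- rec2$fs[[ch]]
    idx <- seq_along(rec2$channels[[ch]])
    slot <- idx > 3 * cfg$tau_seconds * fs & idx <= 4 * cfg$tau_seconds * fs
    rec2$channels[[ch]][!slot] <- 17 * sin(idx[!slot])
  }
  fv_after <- build_feature_vector(rec2, 4)
  expect_identical(fv_before$values, fv_after$values)
})
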