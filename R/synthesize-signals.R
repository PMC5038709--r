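# State-conditioned synthetic biosignal generators.  Each generator returns
# its samples together with the ground-truth fiducials it placed (R peaks,
# SCR events, pulse peaks, EMG gaps) so that the feature extractors can be
# validated by parameter recovery rather than by eye.

# Resolve the per-slot state vector and slot duration for a generator call:
# a single state label means one homogeneous slot spanning the recording.
resolve_states <- function(state, duration_s, tau) {
  if (length(state) > 1) {
    if (is.null(tau)) stop("tau must be supplied with a per-slot state vector")
    list(states = state, tau = tau, duration = length(state) * tau)
  } else {
    list(states = state, tau = duration_s, duration = duration_s)
  }
}

slot_of_time <- function(t, tau, n_slots) pmin(floor(t / tau) + 1L, n_slots)

gauss_bump <- function(t, amp, mu, sd) amp * exp(-((t - mu)^2) / (2 * sd^2))

# P-QRS-T template: five Gaussians with analytically known fiducials.
ecg_template <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amp  = c(0.12, -0.15, 1.00, -0.25, 0.30),
             mu   = c(-0.20, -0.035, 0.00, 0.035, 0.25),
             sd   = c(0.030, 0.012, 0.014, 0.012, 0.050))
}

add_template <- function(samples, fs, center_s, parts, half_width_s) {
  n <- length(samples)
  i0 <- max(1L, floor((center_s - half_width_s) * fs) + 1L)
  i1 <- min(n, ceiling((center_s + half_width_s) * fs) + 1L)
  if (i0 > i1) return(samples)
  tt <- (seq.int(i0, i1) - 1) / fs - center_s
  acc <- 0
  for (k in seq_len(nrow(parts)))
    acc <- acc + gauss_bump(tt, parts$amp[k], parts$mu[k], parts$sd[k])
  samples[i0:i1] <- samples[i0:i1] + acc
  samples
}

# Beat-time schedule shared by ECG and BVP: state-dependent rate and R-R
# jitter, changing at slot boundaries.
sample_beat_times <- function(states, tau, effects) {
  duration <- length(states) * tau
  n_slots <- length(states)
  beats <- numeric(0)
  s1 <- states[1]
  tb <- min(0.5 * 60 / effects[[s1]]$hr_bpm, duration)
  while (tb < duration) {
    beats <- c(beats, tb)
    st <- states[slot_of_time(tb, tau, n_slots)]
    rr <- 60 / effects[[st]]$hr_bpm +
      stats::rnorm(1, 0, effects[[st]]$rr_jitter_sd)
    tb <- tb + max(rr, 0.3)
  }
  beats
}

#' Synthesize a state-conditioned ECG signal
#'
#' Generates an electrocardiogram as a sum-of-Gaussians P-QRS-T template
#' repeated at a state-dependent heart rate with state-dependent R-R
#' jitter (heart-rate variability) plus white noise.  The exact R-peak
#' times are returned as ground truth.
#'
#' @param state A single state label (`"N"`, `"A"`, `"E"`) or a per-slot
#'   state vector (then `tau` gives the slot duration and `duration_s` is
#'   ignored).
#' @param duration_s Recording duration in seconds (single-state call).
#' @param fs Sampling rate in Hz; must be at least 100 to resolve the QRS.
#' @param effects Per-state effect list, see [cohort_config()].
#' @param seed Integer seed.
#' @param noise_sd Additive white-noise standard deviation (mV).
#' @param tau Slot duration when `state` is a vector.
#' @return List with `samples`, `fs`, `beats` (R-peak times in seconds),
#'   `states`, `tau`, `duration_s`.
#' @examples
#' eff <- default_state_effects()
#' eff$N$hr_bpm <- 60; eff$N$rr_jitter_sd <- 0
#' ecg <- synthesize_ecg("N", 10, 250, eff, seed = 1, noise_sd = 0)
#' diff(ecg$beats)   # exactly 1 s apart
#' @export
synthesize_ecg <- function(state, duration_s = NULL, fs = 250,
                           effects = default_state_effects(), seed = 1L,
                           noise_sd = 0.02, tau = NULL) {
  if (fs < 100) stop("fs below 100 Hz cannot resolve the QRS complex")
  if (length(state) == 1 && (is.null(duration_s) || duration_s <= 0))
    stop("duration_s must be > 0")
  rs <- resolve_states(state, duration_s, tau)
  set.seed(as.integer(seed))
  beats <- sample_beat_times(rs$states, rs$tau, effects)
  n <- round(rs$duration * fs)
  samples <- numeric(n)
  tmpl <- ecg_template()
  for (b in beats) samples <- add_template(samples, fs, b, tmpl, 0.45)
  if (noise_sd > 0) samples <- samples + stats::rnorm(n, 0, noise_sd)
  list(samples = samples, fs = fs, beats = beats, states = rs$states,
       tau = rs$tau, duration_s = rs$duration)
}

# SCR bump: fast rise, exponential decay, normalized to unit peak.
scr_shape <- function(x, rise = 0.75, decay = 2.5) {
  g <- (1 - exp(-x / rise)) * exp(-x / decay)
  peak_x <- rise * log(1 + decay / rise)
  g / ((1 - exp(-peak_x / rise)) * exp(-peak_x / decay))
}

#' Synthesize a state-conditioned electrodermal activity signal
#'
#' Tonic skin-conductance baseline (state-dependent level plus slow
#' drift) with Poisson-arriving skin conductance responses (SCR), each a
#' rapid-rise / exponential-decay bump.  Event times and amplitudes are
#' returned as ground truth.
#'
#' @inheritParams synthesize_ecg
#' @param events Optional data frame with columns `time`, `amplitude`
#'   injecting an exact event schedule instead of Poisson sampling.
#' @return List with `samples`, `fs`, `scr_events` (data frame),
#'   `tonic_level`, `states`, `tau`, `duration_s`.
#' @export
synthesize_eda <- function(state, duration_s = NULL, fs = 16,
                           effects = default_state_effects(), seed = 1L,
                           noise_sd = 0.01, tau = NULL, events = NULL) {
  rs <- resolve_states(state, duration_s, tau)
  for (st in unique(rs$states))
    if (effects[[st]]$scr_rate_per_min < 0) stop("negative configured SCR rate")
  set.seed(as.integer(seed))
  n <- round(rs$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  n_slots <- length(rs$states)
  slot_idx <- slot_of_time(tt, rs$tau, n_slots)
  tonic_level <- vapply(rs$states, function(st) effects[[st]]$scl_tonic,
                        numeric(1))
  tonic <- tonic_level[slot_idx]
  if (n_slots > 1) tonic <- moving_average(tonic, min(n, round(5 * fs)))
  drift <- 0.1 * sin(2 * pi * tt / 300 + stats::runif(1, 0, 2 * pi))
  samples <- tonic + drift
  if (is.null(events)) {
    ev_t <- numeric(0); ev_a <- numeric(0)
    for (s in seq_len(n_slots)) {
      rate <- effects[[rs$states[s]]]$scr_rate_per_min
      k <- stats::rpois(1, rate * rs$tau / 60)
      if (k > 0) {
        ev_t <- c(ev_t, sort(stats::runif(k, (s - 1) * rs$tau, s * rs$tau)))
        ev_a <- c(ev_a, stats::runif(k, 0.2, 0.6))
      }
    }
    events <- data.frame(time = ev_t, amplitude = ev_a)
  }
  if (nrow(events) > 0) {
    for (k in seq_len(nrow(events))) {
      x <- tt - events$time[k]
      idx <- x >= 0 & x < 12
      samples[idx] <- samples[idx] + events$amplitude[k] * scr_shape(x[idx])
    }
  }
  if (noise_sd > 0) samples <- samples + stats::rnorm(n, 0, noise_sd)
  list(samples = samples, fs = fs, scr_events = events,
       tonic_level = tonic_level, states = rs$states, tau = rs$tau,
       duration_s = rs$duration)
}

bvp_template <- function(sys_amp, dia_ratio) {
  data.frame(wave = c("M", "Q"),
             amp  = c(sys_amp, sys_amp * dia_ratio),
             mu   = c(0.15, 0.45),
             sd   = c(0.05, 0.07))
}

#' Synthesize a state-conditioned blood volume pulse signal
#'
#' Two-Gaussian pulse template (systolic peak M and diastolic peak Q with
#' the dicrotic notch as the valley between them) repeated at the heart
#' beat times — by default the same beat schedule as [synthesize_ecg()]
#' under the same seed, so both channels of a subject stay aligned.
#'
#' @inheritParams synthesize_ecg
#' @param beats Optional R-peak times (seconds) to lock the pulse to an
#'   existing ECG channel; the pulse transit delay is 0.2 s.
#' @return List with `samples`, `fs`, `fiducials` (data frame of per-beat
#'   M/Q times and amplitudes), `states`, `tau`, `duration_s`.
#' @export
synthesize_bvp <- function(state, duration_s = NULL, fs = 64,
                           effects = default_state_effects(), seed = 1L,
                           noise_sd = 0.02, tau = NULL, beats = NULL) {
  rs <- resolve_states(state, duration_s, tau)
  set.seed(as.integer(seed))
  if (is.null(beats)) beats <- sample_beat_times(rs$states, rs$tau, effects)
  n <- round(rs$duration * fs)
  samples <- numeric(n)
  n_slots <- length(rs$states)
  onset <- beats + 0.2  # pulse transit delay after the R peak
  st <- rs$states[slot_of_time(pmin(beats, rs$duration - 1e-9), rs$tau, n_slots)]
  sys_amp <- vapply(st, function(s) effects[[s]]$bvp_sys_amp, numeric(1))
  dia_ratio <- vapply(st, function(s) effects[[s]]$bvp_dia_ratio, numeric(1))
  for (k in seq_along(beats)) {
    tmpl <- bvp_template(sys_amp[k], dia_ratio[k])
    samples <- add_template(samples, fs, onset[k], tmpl, 0.75)
  }
  if (noise_sd > 0) samples <- samples + stats::rnorm(n, 0, noise_sd)
  fid <- data.frame(beat = beats,
                    m_time = onset + 0.15, q_time = onset + 0.45,
                    sys_amp = sys_amp, dia_amp = sys_amp * dia_ratio)
  list(samples = samples, fs = fs, fiducials = fid, states = rs$states,
       tau = rs$tau, duration_s = rs$duration)
}

#' Synthesize a state-conditioned surface EMG signal
#'
#' Band-limited (20-450 Hz) Gaussian noise whose amplitude envelope
#' alternates active muscle tone and rest gaps.  The gap schedule is
#' state-dependent (psychological tension suppresses EMG gaps) and is
#' returned as ground truth.
#'
#' @inheritParams synthesize_ecg
#' @param rest_amp Envelope level inside gaps and on top of bursts (mV).
#' @param gaps Optional data frame with columns `start`, `duration`
#'   (seconds) forcing an exact gap schedule.
#' @return List with `samples`, `fs`, `gaps` (data frame), `burst_amp`,
#'   `states`, `tau`, `duration_s`.
#' @export
synthesize_emg <- function(state, duration_s = NULL, fs = 1000,
                           effects = default_state_effects(), seed = 1L,
                           rest_amp = 0.002, tau = NULL, gaps = NULL) {
  rs <- resolve_states(state, duration_s, tau)
  set.seed(as.integer(seed))
  n <- round(rs$duration * fs)
  n_slots <- length(rs$states)
  tt <- (seq_len(n) - 1) / fs
  if (is.null(gaps)) {
    g_start <- numeric(0); g_dur <- numeric(0)
    for (s in seq_len(n_slots)) {
      rate <- effects[[rs$states[s]]]$emg_gaps_per_min
      k <- stats::rpois(1, rate * rs$tau / 60)
      if (k > 0) {
        dur <- stats::runif(k, 0.5, 1.5)
        start <- sort(stats::runif(k, (s - 1) * rs$tau,
                                   max((s - 1) * rs$tau, s * rs$tau - max(dur))))
        # drop overlapping gaps (keep earliest)
        keep <- rep(TRUE, k)
        if (k > 1) for (j in 2:k)
          if (start[j] < start[j - 1] + dur[j - 1] + 0.2) keep[j] <- FALSE
        g_start <- c(g_start, start[keep]); g_dur <- c(g_dur, dur[keep])
      }
    }
    gaps <- data.frame(start = g_start, duration = g_dur)
  }
  burst_amp <- vapply(rs$states, function(st) effects[[st]]$emg_burst_amp,
                      numeric(1))
  env <- burst_amp[slot_of_time(tt, rs$tau, n_slots)]
  if (nrow(gaps) > 0)
    for (k in seq_len(nrow(gaps))) {
      idx <- tt >= gaps$start[k] & tt < gaps$start[k] + gaps$duration[k]
      env[idx] <- 0
    }
  env <- env + rest_amp
  # smooth envelope edges (20 ms) so gap onsets are not step discontinuities
  env <- moving_average(env, max(1L, round(0.02 * fs)))
  carrier <- stats::rnorm(n)
  if (fs > 2 * 20) {
    hi <- min(450, 0.45 * fs)
    bf <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
    carrier <- as.numeric(signal::filtfilt(bf, carrier))
  }
  list(samples = env * carrier, fs = fs, gaps = gaps, burst_amp = burst_amp,
       rest_amp = rest_amp, states = rs$states, tau = rs$tau,
       duration_s = rs$duration)
}

#' Sample psychiatric rating-scale scores for a state
#'
#' Each instrument's total score is drawn from a rounded, truncated
#' normal with state-specific mean and sd, clamped to the instrument's
#' published range.  The Hamilton depression item 3 (suicidality,
#' `HRSD3`) is drawn from the state mapping 0 -> Normal, 1-2 -> Atypical,
#' 3-4 -> Emergency rather than from a normal.
#'
#' @param state State label the scores should reflect (a subject's
#'   dominant state; questionnaires are answered at most weekly).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Named integer vector over instruments
#'   (BDI, SSI, BHS, SCST, BIS, BPAQ, BDHI, PHQ9, GAD7, HRSD3).
#' @export
sample_scale_scores <- function(state, config = cohort_config(), seed = 1L) {
  set.seed(as.integer(seed))
  rng <- scale_ranges()
  means <- scaled_scale_means(config)
  out <- integer(0)
  for (inst in names(means)) {
    p <- means[[inst]][[state]]
    x <- round(stats::rnorm(1, p[["mean"]], p[["sd"]]))
    out[inst] <- as.integer(min(max(x, rng[[inst]][1]), rng[[inst]][2]))
  }
  out["HRSD3"] <- switch(state,
                         N = 0L,
                         A = sample(1:2, 1),
                         E = sample(3:4, 1))
  out
}

sample_history_flags <- function(state, config, seed) {
  set.seed(as.integer(seed))
  rates <- config$history_rates
  vapply(names(rates), function(f) stats::runif(1) < rates[[f]][[state]],
         logical(1))
}
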