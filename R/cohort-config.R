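#' Psychiatric state alphabet
#'
#' The three hidden states of the model, ordered by increasing clinical
#' severity: Normal, Atypical, Emergency.
#'
#' @return Character vector `c("N", "A", "E")`.
#' @export
psych_states <- function() c("N", "A", "E")

# Published score ranges of the rating scales carried by the generator.
scale_ranges <- function() {
  list(
    BDI   = c(0, 63),  SSI  = c(0, 38),  BHS  = c(0, 20),
    SCST  = c(0, 40),  BIS  = c(30, 120), BPAQ = c(29, 145),
    BDHI  = c(0, 75),  PHQ9 = c(0, 27),  GAD7 = c(0, 21),
    HRSD3 = c(0, 4)
  )
}

default_scale_score_means <- function() {
  # rows N/A/E: mean, sd per instrument; severity raises every scale.
  mk <- function(mN, mA, mE, sN, sA, sE) {
    list(N = c(mean = mN, sd = sN), A = c(mean = mA, sd = sA),
         E = c(mean = mE, sd = sE))
  }
  list(
    BDI  = mk(8, 22, 40, 5, 7, 8),
    SSI  = mk(2, 10, 24, 2, 5, 6),
    BHS  = mk(4, 9, 15, 3, 4, 3),
    SCST = mk(10, 20, 30, 5, 6, 5),
    BIS  = mk(55, 70, 85, 10, 10, 10),
    BPAQ = mk(60, 80, 100, 15, 15, 15),
    BDHI = mk(20, 35, 50, 8, 10, 10),
    PHQ9 = mk(4, 12, 20, 3, 4, 4),
    GAD7 = mk(4, 10, 16, 3, 4, 3)
    # HRSD item 3 is drawn from the state mapping, not a truncated normal.
  )
}

#' Default per-state signal effect parameters
#'
#' Heart rate and R-R jitter, SCR rate and tonic level, EMG burst
#' amplitude and gap rate, and BVP amplitudes for each state N/A/E.
#' Arousal rises and heart-rate variability and EMG gaps fall with
#' severity.
#'
#' @return Named list over states, each a list of effect fields.
#' @export
default_state_effects <- function() {
  list(
    N = list(hr_bpm = 65, rr_jitter_sd = 0.050, scr_rate_per_min = 2,
             scl_tonic = 2.0, emg_burst_amp = 0.05, emg_gaps_per_min = 8,
             bvp_sys_amp = 1.00, bvp_dia_ratio = 0.50),
    A = list(hr_bpm = 75, rr_jitter_sd = 0.040, scr_rate_per_min = 4,
             scl_tonic = 3.0, emg_burst_amp = 0.08, emg_gaps_per_min = 4,
             bvp_sys_amp = 0.85, bvp_dia_ratio = 0.45),
    E = list(hr_bpm = 90, rr_jitter_sd = 0.025, scr_rate_per_min = 8,
             scl_tonic = 4.5, emg_burst_amp = 0.12, emg_gaps_per_min = 1,
             bvp_sys_amp = 0.70, bvp_dia_ratio = 0.40)
  )
}

default_history_rates <- function() {
  # probability of a positive flag given the subject's dominant state
  list(
    family_suicide_history = c(N = 0.05, A = 0.20, E = 0.45),
    medical_history        = c(N = 0.20, A = 0.40, E = 0.60),
    personal_trait         = c(N = 0.10, A = 0.30, E = 0.60)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Builds and validates the full parameter set of the state-conditioned
#' cohort generator: class balance, slot geometry, sampling rates,
#' state-transition dynamics, per-state signal effects and rating-scale
#' score distributions.
#'
#' The defaults emulate the clinical study conditions the model targets:
#' 55 subjects (14 Emergency, 16 Atypical, 25 Normal dominant labels),
#' psychiatric state resolved at `tau_seconds = 15` second slots, and one
#' prediction window of `window_w = 60` slots (15 minutes) per subject.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param class_counts Named integer vector of dominant-state counts
#'   (`E`, `A`, `N`); must sum to `n_subjects`.
#' @param tau_seconds Slot duration tau in seconds (> 0).
#' @param window_w Number of slots per prediction window (>= 1); the
#'   window spans `T = t + (window_w - 1) * tau`.
#' @param n_windows Windows recorded per subject; recording duration is
#'   `n_windows * window_w * tau_seconds`.
#' @param fs_per_sensor Named sampling rates in Hz for `ecg`, `eda`,
#'   `bvp`, `emg`.
#' @param transition_matrix 3x3 row-stochastic matrix over states N, A, E
#'   used by [sample_state_trajectory()]; cohort trajectories additionally
#'   bias transitions toward each subject's dominant state.
#' @param state_effects Per-state list of signal parameters (heart rate,
#'   R-R jitter sd, SCR rate, tonic skin conductance, EMG burst amplitude
#'   and gap rate, BVP amplitudes).
#' @param scale_score_means Per-instrument, per-state `mean`/`sd` pairs
#'   for the rating scales.
#' @param history_rates Per-flag positive-rate by dominant state.
#' @param effect_scale Multiplier applied to the between-state separation
#'   of all signal effects and scale means (1 = configured effects;
#'   0 = all states identical). Used to study how downstream accuracy
#'   grows with class separation.
#' @param noise_sd Additive white-noise sd per channel (named).
#' @param dominant_floor Minimum fraction of slots a subject spends in
#'   their dominant state.
#' @param seed Integer seed making the whole cohort reproducible.
#' @return An object of class `"cohort_config"` (a validated list).
#' @examples
#' cfg <- cohort_config(n_subjects = 2, class_counts = c(E = 1, A = 0, N = 1),
#'                      window_w = 4)
#' cfg$class_counts
#' @export
cohort_config <- function(n_subjects = 55,
                          class_counts = c(E = 14, A = 16, N = 25),
                          tau_seconds = 15,
                          window_w = 60,
                          n_windows = 1,
                          fs_per_sensor = c(ecg = 250, eda = 16, bvp = 64, emg = 1000),
                          transition_matrix = NULL,
                          state_effects = default_state_effects(),
                          scale_score_means = default_scale_score_means(),
                          history_rates = default_history_rates(),
                          effect_scale = 1,
                          noise_sd = c(ecg = 0.02, eda = 0.01, bvp = 0.02, emg = 0),
                          dominant_floor = 0.6,
                          seed = 1L) {
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(c(0.90, 0.08, 0.02,
                                  0.10, 0.80, 0.10,
                                  0.03, 0.12, 0.85),
                                nrow = 3, byrow = TRUE,
                                dimnames = list(psych_states(), psych_states()))
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    class_counts = class_counts,
    tau_seconds = tau_seconds,
    window_w = as.integer(window_w),
    n_windows = as.integer(n_windows),
    fs_per_sensor = fs_per_sensor,
    transition_matrix = transition_matrix,
    state_effects = state_effects,
    scale_score_means = scale_score_means,
    history_rates = history_rates,
    effect_scale = effect_scale,
    noise_sd = noise_sd,
    dominant_floor = dominant_floor,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_transition_matrix <- function(trans) {
  if (!is.matrix(trans) || nrow(trans) != ncol(trans))
    stop("transition matrix must be square")
  if (any(trans < 0))
    stop("transition matrix entries must be non-negative")
  rs <- rowSums(trans)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  invisible(trans)
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1, cfg$tau_seconds > 0, cfg$window_w >= 1,
            cfg$n_windows >= 1)
  validate_transition_matrix(cfg$transition_matrix)
  if (sum(cfg$class_counts) != cfg$n_subjects)
    stop("class_counts must sum to n_subjects")
  if (any(cfg$class_counts < 0)) stop("class_counts must be non-negative")
  if (!all(c("ecg", "eda", "bvp", "emg") %in% names(cfg$fs_per_sensor)))
    stop("fs_per_sensor must name ecg, eda, bvp, emg")
  if (cfg$fs_per_sensor[["ecg"]] < 100)
    stop("ECG sampling rate below 100 Hz cannot resolve the QRS complex")
  for (st in psych_states()) {
    if (cfg$state_effects[[st]]$scr_rate_per_min < 0)
      stop("configured SCR rate must be non-negative")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic psychiatric cohort configuration\n")
  cat(sprintf("  subjects: %d (E=%d, A=%d, N=%d)\n", x$n_subjects,
              x$class_counts[["E"]], x$class_counts[["A"]], x$class_counts[["N"]]))
  cat(sprintf("  slots: tau = %gs, window = %d slots, %d window(s)/subject\n",
              x$tau_seconds, x$window_w, x$n_windows))
  cat(sprintf("  sampling: ECG %g Hz, EDA %g Hz, BVP %g Hz, EMG %g Hz\n",
              x$fs_per_sensor[["ecg"]], x$fs_per_sensor[["eda"]],
              x$fs_per_sensor[["bvp"]], x$fs_per_sensor[["emg"]]))
  cat(sprintf("  effect scale %g, seed %d\n", x$effect_scale, x$seed))
  invisible(x)
}

# Interpolate per-state effects toward their across-state mean so that
# effect_scale = 0 removes all class separation and 2 doubles it.
scaled_state_effects <- function(cfg) {
  eff <- cfg$state_effects
  s <- cfg$effect_scale
  if (s == 1) return(eff)
  fields <- names(eff$N)
  for (f in fields) {
    mid <- mean(vapply(psych_states(), function(st) eff[[st]][[f]], numeric(1)))
    for (st in psych_states()) {
      eff[[st]][[f]] <- mid + s * (eff[[st]][[f]] - mid)
      if (f %in% c("rr_jitter_sd", "scr_rate_per_min", "scl_tonic",
                   "emg_burst_amp", "emg_gaps_per_min", "bvp_sys_amp",
                   "bvp_dia_ratio"))
        eff[[st]][[f]] <- max(eff[[st]][[f]], 0)
    }
  }
  eff
}

scaled_scale_means <- function(cfg) {
  sc <- cfg$scale_score_means
  s <- cfg$effect_scale
  if (s == 1) return(sc)
  for (inst in names(sc)) {
    mid <- mean(vapply(psych_states(), function(st) sc[[inst]][[st]][["mean"]],
                       numeric(1)))
    for (st in psych_states())
      sc[[inst]][[st]][["mean"]] <- mid + s * (sc[[inst]][[st]][["mean"]] - mid)
  }
  sc
}
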