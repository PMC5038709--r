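#' Sample a psychiatric state trajectory
#'
#' Draws a first-order Markov chain over the states N/A/E: the next
#' state depends exclusively on the current one through the transition
#' matrix.
#'
#' @param config A [cohort_config()], or a bare row-stochastic matrix
#'   with state dimnames.
#' @param n_slots Number of slots to sample (>= 1).
#' @param initial_state Starting state label.
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return Character vector of length `n_slots` over `c("N","A","E")`.
#' @examples
#' tr <- diag(3); dimnames(tr) <- list(c("N","A","E"), c("N","A","E"))
#' sample_state_trajectory(tr, 5, "N", seed = 1)  # absorbing: all N
#' @export
sample_state_trajectory <- function(config, n_slots, initial_state,
                                    seed = 1L) {
  trans <- if (inherits(config, "cohort_config")) config$transition_matrix
           else config
  validate_transition_matrix(trans)
  states <- rownames(trans)
  if (is.null(states)) states <- psych_states()
  stopifnot(n_slots >= 1, initial_state %in% states)
  set.seed(as.integer(seed))
  out <- character(n_slots)
  out[1] <- initial_state
  for (i in seq_len(n_slots - 1) + 1)
    out[i] <- sample(states, 1, prob = trans[out[i - 1], ])
  out
}

# Transition matrix biased toward a subject's dominant state: sticky on
# the dominant state, with excursions that tend to return to it.
dominant_transition <- function(dominant, states = psych_states()) {
  m <- length(states)
  tr <- matrix(0, m, m, dimnames = list(states, states))
  for (s in states) {
    if (s == dominant) {
      tr[s, ] <- 0.15 / (m - 1)
      tr[s, s] <- 0.85
    } else {
      tr[s, ] <- 0.10 / (m - 2 + (m == 2))
      tr[s, s] <- 0.35
      tr[s, dominant] <- 0.55
    }
  }
  tr / rowSums(tr)
}

# Trajectory guaranteed to spend >= floor of its slots in the dominant
# state (rejection with a bounded number of attempts).
dominant_trajectory <- function(dominant, n_slots, floor_frac, seed) {
  tr <- dominant_transition(dominant)
  for (attempt in 1:100) {
    q <- sample_state_trajectory(tr, n_slots, dominant,
                                 seed = seed + attempt - 1L)
    if (mean(q == dominant) >= floor_frac) return(q)
  }
  rep(dominant, n_slots)  # unreachable for sensible configurations
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_subjects` multichannel recordings with the configured
#' dominant-state class balance (default 14 Emergency, 16 Atypical, 25
#' Normal of 55).  Each subject carries a per-slot state trajectory that
#' stays in the dominant state for at least `dominant_floor` of its
#' slots, four biosensor channels whose parameters follow the slot
#' states, rating-scale scores and history flags drawn from the
#' dominant state, and the ground-truth fiducials of every generator.
#' The cohort is byte-identical across calls with the same config.
#'
#' @param config A [cohort_config()].
#' @return Object of class `psych_cohort`: a list of `psych_recording`
#'   objects with the config kept as an attribute.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  subject_seeds <- sample.int(2^31 - 10, n)
  dominants <- rep(c("E", "A", "N"),
                   times = c(config$class_counts[["E"]],
                             config$class_counts[["A"]],
                             config$class_counts[["N"]]))
  n_slots <- config$window_w * config$n_windows
  eff <- scaled_state_effects(config)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    cohort[[i]] <- synthesize_subject(
      subject_id = sprintf("S%02d", i), dominant = dominants[i],
      n_slots = n_slots, config = config, effects = eff,
      seed = subject_seeds[i])
  }
  structure(cohort, class = "psych_cohort", config = config)
}

synthesize_subject <- function(subject_id, dominant, n_slots, config,
                               effects, seed) {
  tau <- config$tau_seconds
  fs <- config$fs_per_sensor
  q <- dominant_trajectory(dominant, n_slots, config$dominant_floor, seed)
  ecg <- synthesize_ecg(q, fs = fs[["ecg"]], effects = effects,
                        seed = seed + 1L, noise_sd = config$noise_sd[["ecg"]],
                        tau = tau)
  eda <- synthesize_eda(q, fs = fs[["eda"]], effects = effects,
                        seed = seed + 2L, noise_sd = config$noise_sd[["eda"]],
                        tau = tau)
  bvp <- synthesize_bvp(q, fs = fs[["bvp"]], effects = effects,
                        seed = seed + 3L, noise_sd = config$noise_sd[["bvp"]],
                        tau = tau, beats = ecg$beats)
  emg <- synthesize_emg(q, fs = fs[["emg"]], effects = effects,
                        seed = seed + 4L, tau = tau)
  structure(list(
    subject_id = subject_id,
    channels = list(ecg = ecg$samples, eda = eda$samples,
                    bvp = bvp$samples, emg = emg$samples),
    fs = fs,
    scale_scores = sample_scale_scores(dominant, config, seed = seed + 5L),
    history = sample_history_flags(dominant, config, seed = seed + 6L),
    true_states = q,
    dominant = dominant,
    tau = tau,
    window_w = config$window_w,
    ground_truth = list(beats = ecg$beats, scr_events = eda$scr_events,
                        bvp_fiducials = bvp$fiducials, emg_gaps = emg$gaps)
  ), class = "psych_recording")
}

#' @export
print.psych_cohort <- function(x, ...) {
  dom <- vapply(x, function(r) r$dominant, character(1))
  cat(sprintf("Synthetic psychiatric cohort: %d subjects (E=%d, A=%d, N=%d)\n",
              length(x), sum(dom == "E"), sum(dom == "A"), sum(dom == "N")))
  if (length(x) > 0)
    cat(sprintf("  %d slots of %gs per subject; channels: %s\n",
                length(x[[1]]$true_states), x[[1]]$tau,
                paste(names(x[[1]]$channels), collapse = ", ")))
  invisible(x)
}

#' @export
print.psych_recording <- function(x, ...) {
  cat(sprintf("Recording %s: dominant state %s, %d slots of %gs\n",
              x$subject_id, x$dominant, length(x$true_states), x$tau))
  for (ch in names(x$channels))
    cat(sprintf("  %s: %d samples at %g Hz\n", ch, length(x$channels[[ch]]),
                x$fs[[ch]]))
  invisible(x)
}

#' Write a cohort to its on-disk layout
#'
#' One directory per subject containing `signals.csv` (long format:
#' `channel`, `t_seconds`, `value`), `meta.json` (sampling rates, scale
#' scores, history flags, dominant state, slot duration) and
#' `states.csv` (`slot_index`, `state`).
#'
#' @param cohort A `psych_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort) {
    sd <- file.path(dir, rec$subject_id)
    dir.create(sd, showWarnings = FALSE)
    sig <- do.call(rbind, lapply(names(rec$channels), function(ch) {
      x <- rec$channels[[ch]]
      data.frame(channel = ch,
                 t_seconds = (seq_along(x) - 1) / rec$fs[[ch]],
                 value = x)
    }))
    utils::write.csv(sig, file.path(sd, "signals.csv"), row.names = FALSE)
    meta <- list(fs = as.list(rec$fs),
                 scale_scores = as.list(rec$scale_scores),
                 history = as.list(rec$history),
                 dominant = rec$dominant, tau = rec$tau,
                 window_w = rec$window_w)
    jsonlite::write_json(meta, file.path(sd, "meta.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(data.frame(slot_index = seq_along(rec$true_states),
                                state = rec$true_states),
                     file.path(sd, "states.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from its on-disk layout
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `psych_cohort` (generator ground truth is not persisted and
#'   is `NULL` after a round trip).
#' @export
read_cohort <- function(dir) {
  subs <- sort(list.dirs(dir, recursive = FALSE))
  cohort <- lapply(subs, function(sd) {
    sig <- utils::read.csv(file.path(sd, "signals.csv"))
    meta <- jsonlite::read_json(file.path(sd, "meta.json"),
                                simplifyVector = TRUE)
    st <- utils::read.csv(file.path(sd, "states.csv"))
    channels <- split(sig$value, sig$channel)
    channels <- channels[intersect(c("ecg", "eda", "bvp", "emg"),
                                   names(channels))]
    structure(list(
      subject_id = basename(sd),
      channels = channels,
      fs = unlist(meta$fs),
      scale_scores = unlist(meta$scale_scores),
      history = unlist(meta$history),
      true_states = st$state[order(st$slot_index)],
      dominant = meta$dominant,
      tau = meta$tau,
      window_w = meta$window_w,
      ground_truth = NULL
    ), class = "psych_recording")
  })
  structure(cohort, class = "psych_cohort")
}
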