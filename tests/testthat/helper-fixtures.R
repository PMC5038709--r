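# Shared fixtures: tiny cohorts, reference HMMs, and brute-force oracles
# kept independent of the implementation paths they check.

tiny_cohort_config <- function(seed = 7, effect_scale = 1,
                               n_subjects = 9,
                               class_counts = c(E = 3, A = 3, N = 3)) {
  cohort_config(n_subjects = n_subjects, class_counts = class_counts,
                tau_seconds = 10, window_w = 12,
                fs_per_sensor = c(ecg = 200, eda = 16, bvp = 64, emg = 400),
                effect_scale = effect_scale, seed = seed)
}

uniform3 <- function() {
  tr <- matrix(1 / 3, 3, 3, dimnames = list(c("N", "A", "E"),
                                            c("N", "A", "E")))
  tr
}

# Reference lambda with well-separated emissions over a 6-symbol codebook.
known_hmm <- function() {
  trans <- matrix(c(0.80, 0.15, 0.05,
                    0.10, 0.80, 0.10,
                    0.05, 0.25, 0.70), 3, byrow = TRUE)
  emis <- matrix(c(0.60, 0.20, 0.10, 0.05, 0.03, 0.02,
                   0.05, 0.10, 0.60, 0.15, 0.05, 0.05,
                   0.02, 0.03, 0.05, 0.10, 0.20, 0.60), 3, byrow = TRUE)
  hmm_params(c(0.5, 0.3, 0.2), trans, emis)
}

random_dirichlet_rows <- function(nr, nc) {
  x <- matrix(stats::rgamma(nr * nc, 1), nr, nc)
  sweep(x, 1, rowSums(x), "/")
}

random_hmm <- function(m = 3, K = 4) {
  hmm_params(as.numeric(random_dirichlet_rows(1, m)),
             random_dirichlet_rows(m, m),
             random_dirichlet_rows(m, K),
             states = if (m == 3) c("N", "A", "E") else paste0("s", 1:m))
}

# Independent max-product oracle: enumerate every state path.
brute_force_viterbi <- function(params, obs) {
  m <- length(params$states)
  Tn <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(m)), Tn)))
  lp <- apply(paths, 1, function(p) {
    v <- log(params$pi[p[1]]) + log(params$emis[p[1], obs[1]])
    if (Tn > 1) for (t in 2:Tn)
      v <- v + log(params$trans[p[t - 1], p[t]]) +
        log(params$emis[p[t], obs[t]])
    v
  })
  best <- max(lp)
  list(logp = best, n_best = sum(abs(lp - best) < 1e-12),
       path = params$states[paths[which.max(lp), ]])
}

table1_sequence <- function() c("N", "N", "A", "E", "E", "E", "A", "E", "E", "A")

within_effects <- function(eff, state, ...) {
  mods <- list(...)
  for (nm in names(mods)) eff[[state]][[nm]] <- mods[[nm]]
  eff
}
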