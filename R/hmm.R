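# Hidden Markov model over the psychiatric states: lambda = {pi, T', E'}
# with discrete codebook emissions (default) or per-state diagonal
# Gaussian emissions over discriminant features.

LOG_FLOOR <- -1e9

safe_log <- function(p) ifelse(p > 0, log(p), LOG_FLOOR)

#' Construct and validate HMM parameters
#'
#' @param pi Initial state probabilities (length m, sums to 1).
#' @param trans m x m row-stochastic transition matrix.
#' @param emis m x K emission matrix (discrete codebook emissions), or
#'   `NULL` for Gaussian emissions.
#' @param states Ordered state labels; ties in decoding break toward
#'   the earlier label.
#' @param gauss Optional list with `mean` (m x d) and `var` (m x d,
#'   floored at 1e-6) for Gaussian emissions.
#' @return Object of class `hmm_params`.
#' @export
hmm_params <- function(pi, trans, emis = NULL, states = psych_states(),
                       gauss = NULL) {
  m <- length(states)
  stopifnot(length(pi) == m, nrow(trans) == m, ncol(trans) == m)
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1")
  if (any(pi < 0) || any(trans < 0)) stop("probabilities must be >= 0")
  if (any(abs(rowSums(trans) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  if (!is.null(emis)) {
    stopifnot(nrow(emis) == m)
    if (any(emis < 0)) stop("emission probabilities must be >= 0")
    if (any(abs(rowSums(emis) - 1) > 1e-9))
      stop("emission rows must sum to 1")
  }
  if (!is.null(gauss)) gauss$var <- pmax(gauss$var, 1e-6)
  structure(list(states = states, pi = stats::setNames(pi, states),
                 trans = structure(trans, dimnames = list(states, states)),
                 emis = emis, gauss = gauss,
                 emis_type = if (is.null(gauss)) "discrete" else "gaussian"),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, digits = 3, ...) {
  cat("HMM over states {", paste(x$states, collapse = ", "), "}\n", sep = "")
  cat("initial:\n"); print(round(x$pi, digits))
  cat("transitions:\n"); print(round(x$trans, digits))
  if (x$emis_type == "discrete")
    cat("emissions: ", ncol(x$emis), "-symbol codebook\n", sep = "")
  else cat("emissions: diagonal-Gaussian,", ncol(x$gauss$mean), "dims\n")
  invisible(x)
}

# T x m matrix of per-slot log emission probabilities.
emission_logprob <- function(params, obs) {
  if (params$emis_type == "discrete") {
    obs <- as.integer(obs)
    t(safe_log(params$emis)[, obs, drop = FALSE])
  } else {
    obs <- as.matrix(obs)
    m <- length(params$states)
    out <- matrix(0, nrow(obs), m)
    for (s in seq_len(m))
      out[, s] <- rowSums(stats::dnorm(obs,
                                       matrix(params$gauss$mean[s, ],
                                              nrow(obs), ncol(obs), byrow = TRUE),
                                       matrix(sqrt(params$gauss$var[s, ]),
                                              nrow(obs), ncol(obs), byrow = TRUE),
                                       log = TRUE))
    out
  }
}

#' Quantize feature vectors into a discrete codebook
#'
#' k-means codebook over the (discriminant) feature vectors; each vector
#' maps to its nearest centroid's symbol.  Deterministic for a fixed
#' seed.  When `K` is at least the number of distinct vectors, every
#' distinct vector becomes its own symbol (zero quantization error).
#'
#' @param x Numeric matrix of feature vectors (rows = slots).
#' @param K Codebook size.
#' @param seed Integer seed.
#' @return List with `symbols` (integers in 1..K) and `codebook`
#'   (K x d centroid matrix).
#' @export
quantize_observations <- function(x, K, seed = 1L) {
  x <- as.matrix(x)
  ux <- unique(x)
  set.seed(as.integer(seed))
  if (K >= nrow(ux)) {
    codebook <- ux
  } else {
    km <- stats::kmeans(x, centers = K, nstart = 5, iter.max = 100)
    codebook <- km$centers
  }
  rownames(codebook) <- NULL
  list(symbols = apply_quantize(codebook, x), codebook = codebook)
}

#' @rdname quantize_observations
#' @param codebook Centroid matrix from a previous fit.
#' @export
apply_quantize <- function(codebook, x) {
  x <- as.matrix(x)
  d2 <- outer(rowSums(x^2), rowSums(codebook^2), "+") -
    2 * tcrossprod(x, codebook)
  max.col(-d2, ties.method = "first")
}

#' Train an HMM by Viterbi path counting
#'
#' Learns lambda in a single pass over the dataset.  In supervised mode
#' (labels given) the initial states, transitions and emissions are
#' counted directly along the labeled paths.  In unsupervised mode the
#' parameters start uniform with a small jitter, each sequence's
#' Viterbi path is computed once, and counts are taken along those
#' decoded paths.  Counts plus a smoothing pseudo-count are normalized
#' into probabilities.
#'
#' @param sequences List of integer symbol vectors (1..K).
#' @param labels Optional list of state-label vectors aligned with
#'   `sequences` (supervised mode).
#' @param m Number of states.
#' @param K Codebook size; defaults to the largest observed symbol.
#' @param smoothing Laplace pseudo-count added to every cell.
#' @param states State labels (default `c("N","A","E")` for m = 3).
#' @param seed Seed for the unsupervised jittered initialization.
#' @return An [hmm_params()] object.
#' @export
vpc_train <- function(sequences, labels = NULL, m = 3, K = NULL,
                      smoothing = 1, states = NULL, seed = 1L) {
  if (length(sequences) == 0) stop("sequences must be non-empty")
  if (is.null(K)) K <- max(unlist(sequences))
  if (is.null(states)) states <- if (m == 3) psych_states() else paste0("s", 1:m)
  if (!is.null(labels)) {
    if (length(labels) != length(sequences))
      stop("labels and sequences must align")
    lens_ok <- mapply(function(s, l) length(s) == length(l), sequences, labels)
    if (!all(lens_ok)) stop("label/sequence length mismatch")
    paths <- labels
  } else {
    init <- jittered_uniform_hmm(m, K, states, seed)
    paths <- lapply(sequences, function(s) viterbi_decode(init, s)$path)
  }
  count_hmm(sequences, paths, m, K, smoothing, states)
}

count_hmm <- function(sequences, paths, m, K, smoothing, states) {
  pi_c <- stats::setNames(numeric(m), states)
  tr_c <- matrix(0, m, m, dimnames = list(states, states))
  em_c <- matrix(0, m, K, dimnames = list(states, NULL))
  for (i in seq_along(sequences)) {
    p <- as.character(paths[[i]])
    o <- as.integer(sequences[[i]])
    pi_c[p[1]] <- pi_c[p[1]] + 1
    if (length(p) > 1)
      for (t in 2:length(p)) tr_c[p[t - 1], p[t]] <- tr_c[p[t - 1], p[t]] + 1
    for (t in seq_along(o)) em_c[p[t], o[t]] <- em_c[p[t], o[t]] + 1
  }
  norm_rows <- function(x, s) {
    x <- x + s
    sweep(x, 1, rowSums(x), "/")
  }
  pi <- (pi_c + smoothing) / sum(pi_c + smoothing)
  hmm_params(pi, norm_rows(tr_c, smoothing), norm_rows(em_c, smoothing),
             states)
}

jittered_uniform_hmm <- function(m, K, states, seed, jitter = 0.01) {
  set.seed(as.integer(seed))
  jit <- function(nr, nc) {
    x <- 1 + jitter * matrix(stats::rgamma(nr * nc, 1), nr, nc)
    sweep(x, 1, rowSums(x), "/")
  }
  hmm_params(as.numeric(jit(1, m)), jit(m, m), jit(m, K), states)
}

# Scaled forward-backward under (possibly unnormalized) parameter
# weights; returns per-slot posteriors, summed transition posteriors,
# emission posterior counts and the log-likelihood.
forward_backward <- function(w_pi, A, B, obs) {
  obs <- as.integer(obs)
  Tn <- length(obs)
  m <- length(w_pi)
  alpha <- matrix(0, Tn, m); cvec <- numeric(Tn)
  a <- w_pi * B[, obs[1]]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A)[1, ] * B[, obs[t]]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, m); beta[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1)
    beta[t, ] <- (A %*% (B[, obs[t + 1]] * beta[t + 1, ]))[, 1] / cvec[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, m, m)
  if (Tn > 1) for (t in 2:Tn)
    xi <- xi + (alpha[t - 1, ] %o% (B[, obs[t]] * beta[t, ])) * A / cvec[t]
  list(gamma = gamma, xi = xi, loglik = sum(log(cvec)))
}

#' Log-likelihood of an observation sequence
#'
#' Scaled forward-algorithm log-likelihood of a symbol sequence under
#' the model.
#'
#' @param params An [hmm_params()] object with discrete emissions.
#' @param obs Integer symbol vector.
#' @return Log-likelihood.
#' @export
forward_loglik <- function(params, obs) {
  forward_backward(params$pi, params$trans, params$emis, obs)$loglik
}

#' Train an HMM by stochastic variational inference
#'
#' Dirichlet-prior variational posteriors over the initial, transition
#' and emission rows are updated by noisy natural-gradient steps: each
#' iteration samples a mini-batch of sequences, computes expected
#' sufficient statistics by forward-backward under the current
#' variational geometric means, scales them to the full dataset size,
#' and blends the old and new natural parameters with step size
#' `rho_i = learning_rate * i^(-kappa)`.  Per-iteration cost depends on
#' the batch, not the dataset, which is what makes the algorithm scale.
#'
#' @param sequences List of integer symbol vectors.
#' @param m Number of states.
#' @param K Codebook size; defaults to the largest observed symbol.
#' @param batch_size Mini-batch size (default 11 sequences).
#' @param learning_rate Initial step size (default 0.9).
#' @param kappa Forgetting rate of the step-size schedule (default 0.6).
#' @param n_iterations Number of stochastic updates.
#' @param prior Symmetric Dirichlet prior concentration.
#' @param states State labels.
#' @param seed Integer seed (initialization and batch draws).
#' @return An [hmm_params()] object (variational means), with the
#'   jittered initialization kept in the `"init"` attribute.
#' @export
svi_train <- function(sequences, m = 3, K = NULL, batch_size = 11,
                      learning_rate = 0.9, kappa = 0.6, n_iterations = 100,
                      prior = 1, states = NULL, seed = 1L) {
  n <- length(sequences)
  if (batch_size > n) stop("batch_size exceeds the number of sequences")
  if (is.null(K)) K <- max(unlist(sequences))
  if (is.null(states)) states <- if (m == 3) psych_states() else paste0("s", 1:m)
  set.seed(as.integer(seed))
  jit <- function(nr, nc) prior + 0.5 * matrix(stats::rgamma(nr * nc, 1), nr, nc)
  u_pi <- jit(1, m)[1, ]
  u_tr <- jit(m, m)
  u_em <- jit(m, K)
  init_means <- list(pi = u_pi / sum(u_pi),
                     trans = sweep(u_tr, 1, rowSums(u_tr), "/"),
                     emis = sweep(u_em, 1, rowSums(u_em), "/"))
  elog <- function(u) {
    if (is.matrix(u)) exp(digamma(u) - digamma(rowSums(u)))
    else exp(digamma(u) - digamma(sum(u)))
  }
  for (i in seq_len(n_iterations)) {
    rho <- learning_rate * i^(-kappa)
    batch <- sample.int(n, batch_size)
    w_pi <- elog(u_pi); A <- elog(u_tr); B <- elog(u_em)
    s_pi <- numeric(m); s_tr <- matrix(0, m, m); s_em <- matrix(0, m, K)
    for (b in batch) {
      o <- as.integer(sequences[[b]])
      fb <- forward_backward(w_pi, A, B, o)
      s_pi <- s_pi + fb$gamma[1, ]
      s_tr <- s_tr + fb$xi
      for (t in seq_along(o)) s_em[, o[t]] <- s_em[, o[t]] + fb$gamma[t, ]
    }
    scale <- n / batch_size
    u_pi <- (1 - rho) * u_pi + rho * (prior + scale * s_pi)
    u_tr <- (1 - rho) * u_tr + rho * (prior + scale * s_tr)
    u_em <- (1 - rho) * u_em + rho * (prior + scale * s_em)
  }
  out <- hmm_params(u_pi / sum(u_pi), sweep(u_tr, 1, rowSums(u_tr), "/"),
                    sweep(u_em, 1, rowSums(u_em), "/"), states)
  attr(out, "init") <- init_means
  attr(out, "posterior") <- list(pi = u_pi, trans = u_tr, emis = u_em)
  out
}

#' Viterbi decoding of the most likely state sequence
#'
#' Max-product dynamic programming in log space with backpointers;
#' returns the globally most probable hidden-state path and its log
#' joint probability.  Argmax ties break toward the earlier state in
#' `params$states` (severity order N < A < E).  Observations with zero
#' probability under every state are decoded through a log floor and
#' flagged.
#'
#' @param params An [hmm_params()] object.
#' @param obs Integer symbol vector (discrete emissions) or a numeric
#'   matrix of per-slot feature vectors (Gaussian emissions).
#' @return List with `path` (state labels), `logp`, and `flagged`.
#' @export
viterbi_decode <- function(params, obs) {
  le <- emission_logprob(params, obs)
  Tn <- nrow(le)
  m <- ncol(le)
  flagged <- any(apply(le, 1, max) <= LOG_FLOOR)
  lpi <- safe_log(params$pi)
  ltr <- safe_log(params$trans)
  delta <- matrix(LOG_FLOOR, Tn, m)
  back <- matrix(1L, Tn, m)
  delta[1, ] <- lpi + le[1, ]
  if (Tn > 1) for (t in 2:Tn) {
    for (s in seq_len(m)) {
      cand <- delta[t - 1, ] + ltr[, s]
      back[t, s] <- which.max(cand)
      delta[t, s] <- cand[back[t, s]] + le[t, s]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) path[t] <- back[t + 1, path[t + 1]]
  list(path = params$states[path], logp = max(delta[Tn, ]), flagged = flagged)
}

#' Greedy per-step state decoding
#'
#' The literal step-wise reading of the prediction recurrence: the first
#' state maximizes initial times emission probability; each subsequent
#' state maximizes transition-from-the-previously-chosen-state times
#' emission, with no backtracking.  Provided alongside [viterbi_decode()]
#' so the two readings can be compared; Viterbi is the package default.
#'
#' @inheritParams viterbi_decode
#' @return Character vector of state labels.
#' @export
greedy_decode <- function(params, obs) {
  le <- emission_logprob(params, obs)
  Tn <- nrow(le)
  lpi <- safe_log(params$pi)
  ltr <- safe_log(params$trans)
  path <- integer(Tn)
  path[1] <- which.max(lpi + le[1, ])
  if (Tn > 1) for (t in 2:Tn)
    path[t] <- which.max(ltr[path[t - 1], ] + le[t, ])
  params$states[path]
}

#' Simulate states and symbols from an HMM
#'
#' @param params An [hmm_params()] object with discrete emissions.
#' @param n_slots Sequence length.
#' @param seed Integer seed.
#' @return List with `states` (labels) and `symbols` (integers).
#' @export
simulate_hmm <- function(params, n_slots, seed = 1L) {
  set.seed(as.integer(seed))
  m <- length(params$states)
  K <- ncol(params$emis)
  st <- integer(n_slots); sy <- integer(n_slots)
  st[1] <- sample.int(m, 1, prob = params$pi)
  for (t in seq_len(n_slots)) {
    if (t > 1) st[t] <- sample.int(m, 1, prob = params$trans[st[t - 1], ])
    sy[t] <- sample.int(K, 1, prob = params$emis[st[t], ])
  }
  list(states = params$states[st], symbols = sy)
}
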