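#' Fit the psychiatric state prediction model
#'
#' The main fitting function: takes a slot-level feature table (from
#' [cohort_features()]), fits the feature pipeline (median imputation,
#' min-max normalization, mRMR selection, PCA, kernel discriminant
#' analysis), quantizes the discriminant scores into a k-means codebook,
#' and trains the three-state hidden Markov model over the resulting
#' symbol sequences — by supervised Viterbi path counting (default) or
#' by stochastic variational inference.
#'
#' @param features Feature table with columns `subject`, `slot`,
#'   `true_state` plus feature columns (see [cohort_features()]).
#' @param algo Training algorithm: `"vpc"` (Viterbi path counting) or
#'   `"svi"` (stochastic variational inference).
#' @param supervised For `"vpc"`: use the per-slot state labels
#'   (default) or decode-and-count unsupervised.
#' @param groups Optional character vector of feature groups to use
#'   (e.g. `c("ECG","EDA","MH","FH","PT")`); `NULL` uses everything.
#' @param k_features,n_bins,pca_var,kernel,eps,gda_max_points Pipeline
#'   settings, see [fit_pipeline()].
#' @param codebook_size Number of emission symbols K.
#' @param smoothing Laplace pseudo-count for path counting.
#' @param batch_size,learning_rate,kappa,n_iterations SVI settings, see
#'   [svi_train()].
#' @param seed Integer seed controlling every stochastic step.
#' @return Object of class `psychstate` with methods `print`,
#'   `summary`, `coef`, `predict`, `simulate` and `plot`.
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_subjects = 6, class_counts = c(E = 2, A = 2, N = 2),
#'                      tau_seconds = 10, window_w = 6,
#'                      fs_per_sensor = c(ecg = 200, eda = 16, bvp = 64,
#'                                        emg = 400))
#' feats <- cohort_features(generate_cohort(cfg))
#' fit <- psychstate(feats, seed = 1)
#' predict(fit, feats)
#' }
#' @export
psychstate <- function(features, algo = c("vpc", "svi"), supervised = TRUE,
                       groups = NULL, k_features = 30, n_bins = 10,
                       pca_var = 0.95, kernel = "rbf", eps = 1e-6,
                       gda_max_points = 750, codebook_size = 16,
                       smoothing = 1, batch_size = 11, learning_rate = 0.9,
                       kappa = 0.6, n_iterations = 200, seed = 1L) {
  algo <- match.arg(algo)
  seed <- as.integer(seed)
  fcols <- select_feature_columns(features, groups)
  x <- as.matrix(features[, fcols, drop = FALSE])
  usable <- colSums(!is.na(x)) > 0
  x <- x[, usable, drop = FALSE]
  labels <- features$true_state
  pipeline <- fit_pipeline(x, labels, k_features = k_features,
                           n_bins = n_bins, pca_var = pca_var,
                           kernel = kernel, eps = eps,
                           gda_max_points = gda_max_points, seed = seed)
  qz <- quantize_observations(pipeline$scores, codebook_size,
                              seed = seed + 1L)
  split_idx <- split(seq_len(nrow(features)), features$subject)
  split_idx <- split_idx[order(names(split_idx))]
  sequences <- lapply(split_idx, function(i) qz$symbols[i[order(features$slot[i])]])
  slot_labels <- lapply(split_idx, function(i) labels[i[order(features$slot[i])]])
  K <- nrow(qz$codebook)
  hmm <- if (algo == "vpc") {
    vpc_train(sequences, labels = if (supervised) slot_labels else NULL,
              m = 3, K = K, smoothing = smoothing, seed = seed + 2L)
  } else {
    svi_train(sequences, m = 3, K = K, batch_size = min(batch_size,
                                                        length(sequences)),
              learning_rate = learning_rate, kappa = kappa,
              n_iterations = n_iterations, seed = seed + 2L)
  }
  structure(list(pipeline = pipeline, codebook = qz$codebook, hmm = hmm,
                 states = psych_states(), algo = algo,
                 supervised = supervised, groups = groups,
                 feature_names = colnames(x),
                 train_scores = pipeline$scores, train_labels = labels,
                 seed = seed, call = match.call()),
            class = "psychstate")
}

select_feature_columns <- function(features, groups) {
  fcols <- feature_columns(features)
  if (is.null(groups)) return(fcols)
  gm <- attr(features, "groups")
  if (is.null(gm)) gm <- feature_groups()
  fcols[gm[fcols] %in% groups]
}

#' Predict window-level psychiatric states
#'
#' Transforms new slot-level features through the stored pipeline and
#' codebook, splits each subject's slots into observation windows,
#' Viterbi-decodes each window and applies the candidate ensemble with
#' majority voting.
#'
#' @param object A fitted [psychstate()] model.
#' @param newdata Feature table like the training one.
#' @param window_w Slots per prediction window; `NULL` treats each
#'   subject's whole recording as one window.
#' @param ... Unused.
#' @return Data frame with one row per subject-window: the prediction,
#'   the three candidates, the decoded sequence, the path
#'   log-probability and per-class scores (vote share scaled by the
#'   per-slot geometric-mean path probability) for ROC analysis.
#' @export
predict.psychstate <- function(object, newdata, window_w = NULL, ...) {
  scores <- stats::predict(object$pipeline,
                           as.matrix(newdata[, object$feature_names,
                                             drop = FALSE]))
  symbols <- apply_quantize(object$codebook, scores)
  split_idx <- split(seq_len(nrow(newdata)), newdata$subject)
  rows <- list()
  for (subj in names(split_idx)) {
    i <- split_idx[[subj]][order(newdata$slot[split_idx[[subj]]])]
    w <- if (is.null(window_w)) length(i) else window_w
    starts <- seq(1, length(i), by = w)
    for (s in starts) {
      idx <- i[s:min(s + w - 1, length(i))]
      pr <- predict_window(object$hmm, symbols[idx])
      conf <- exp(pr$logp / length(idx))
      sc <- (pr$vote_counts / 3) * conf
      rows[[length(rows) + 1]] <- data.frame(
        subject = subj, window_start_slot = newdata$slot[idx[1]],
        predicted = pr$predicted,
        lrl = pr$lrl_candidate$state, hfc = pr$hfc_candidate$state,
        mrs = pr$mrs_candidate,
        decoded = paste(pr$decoded, collapse = ""),
        logp = pr$logp,
        score_N = sc[["N"]], score_A = sc[["A"]], score_E = sc[["E"]])
    }
  }
  do.call(rbind, rows)
}

#' @export
coef.psychstate <- function(object, ...) {
  list(pi = object$hmm$pi, trans = object$hmm$trans, emis = object$hmm$emis)
}

#' @export
print.psychstate <- function(x, ...) {
  cat("Psychiatric state prediction model (", toupper(x$algo),
      if (x$algo == "vpc") if (x$supervised) ", supervised" else ", unsupervised",
      ")\n", sep = "")
  print(x$pipeline)
  cat("codebook: ", nrow(x$codebook), " symbols; trained on ",
      length(unique(x$train_labels)), " states, ",
      length(x$train_labels), " slots\n", sep = "")
  invisible(x)
}

#' @export
summary.psychstate <- function(object, ...) {
  print(object)
  print(object$hmm)
  occ <- table(object$train_labels)
  cat("training slot occupancy:",
      paste(names(occ), occ, sep = "=", collapse = " "), "\n")
  invisible(object)
}

#' Simulate state and symbol sequences from a fitted model
#'
#' @param object A fitted [psychstate()] model.
#' @param nsim Number of sequences.
#' @param seed Integer seed.
#' @param n_slots Sequence length (default the training window length).
#' @param ... Unused.
#' @return List of `simulate_hmm()` results (`states`, `symbols`).
#' @export
simulate.psychstate <- function(object, nsim = 1, seed = 1L, n_slots = 60,
                                ...) {
  lapply(seq_len(nsim), function(i)
    simulate_hmm(object$hmm, n_slots, seed = as.integer(seed) + i - 1L))
}

#' Plot the discriminant scores of the training data
#'
#' Scatter of the first two kernel discriminant components, colored by
#' the true slot state — the package's view of how well the classes
#' concentrate after the pipeline.
#'
#' @param x A fitted [psychstate()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psychstate <- function(x, ...) {
  sc <- x$train_scores
  cols <- c(N = "#2b8cbe", A = "#fdae61", E = "#d7191c")
  if (ncol(sc) == 1) sc <- cbind(sc, seq_len(nrow(sc)))
  graphics::plot(sc[, 1], sc[, 2], col = cols[x$train_labels], pch = 16,
                 cex = 0.6, xlab = "discriminant 1",
                 ylab = if (ncol(x$train_scores) > 1) "discriminant 2" else "slot",
                 main = "Kernel discriminant scores by state", ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 16)
  invisible(x)
}
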