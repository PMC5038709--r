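#' Subject-stratified k-fold cross-validation
#'
#' Splits subjects (never slots) into k folds stratified by dominant
#' state label, fits the full pipeline and HMM on the training folds
#' only, predicts the held-out subjects' windows and pools everything
#' into one diagnostic report.  A subject's windows can therefore never
#' appear in both train and test.
#'
#' @param features Slot-level feature table from [cohort_features()]
#'   (needs `subject`, `slot`, `true_state`; `dominant` is recomputed
#'   from the slot labels if absent).
#' @param k Number of folds (>= 2); `k = `number of subjects gives
#'   leave-one-subject-out.
#' @param algo,groups,seed,window_w,... Passed to [psychstate()] /
#'   [predict.psychstate()].
#' @return A `psych_report` with the pooled predictions in
#'   `$predictions` and the fold assignment in `$folds`.
#' @export
cross_validate <- function(features, k = 5, algo = "vpc", groups = NULL,
                           seed = 1L, window_w = NULL, ...) {
  stopifnot(k >= 2)
  seed <- as.integer(seed)
  subjects <- sort(unique(features$subject))
  dominant <- vapply(subjects, function(s) {
    st <- features$true_state[features$subject == s]
    names(which.max(table(st)))
  }, character(1))
  folds <- stratified_folds(subjects, dominant, k, seed)
  for (f in seq_len(k)) {
    train_classes <- unique(dominant[folds != f])
    if (!all(unique(dominant) %in% train_classes))
      stop("a class is absent from the training subjects of fold ", f,
           "; choose a smaller k")
  }
  preds <- list()
  for (f in seq_len(k)) {
    test_subj <- subjects[folds == f]
    if (length(test_subj) == 0) next
    train_rows <- features$subject %in% subjects[folds != f]
    fit <- psychstate(features[train_rows, , drop = FALSE], algo = algo,
                      groups = groups, seed = seed + f, ...)
    p <- stats::predict(fit, features[!train_rows, , drop = FALSE],
                        window_w = window_w)
    p$truth <- dominant[p$subject]
    p$fold <- f
    preds[[f]] <- p
  }
  preds <- do.call(rbind, preds)
  scores <- as.matrix(preds[, c("score_N", "score_A", "score_E")])
  colnames(scores) <- psych_states()
  report <- diagnostic_report(preds$truth, preds$predicted, scores)
  report$predictions <- preds
  report$folds <- stats::setNames(folds, subjects)
  report
}

stratified_folds <- function(subjects, dominant, k, seed) {
  set.seed(seed)
  folds <- integer(length(subjects))
  for (cl in unique(dominant)) {
    idx <- which(dominant == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Nested sensor masks mirroring an incremental ablation
#'
#' Feature-group masks that start from the patient-history flags alone
#' and add one sensor at a time (EDA, then ECG, then BVP, then EMG) —
#' the ordering used to check that each added sensor never hurts the
#' pooled sensitivity plus specificity.
#'
#' @return Named list of group vectors for [cross_validate()]'s
#'   `groups`.
#' @export
sensor_ablation_masks <- function() {
  hist <- c("MH", "FH", "PT")
  list(history          = hist,
       history_eda      = c(hist, "EDA"),
       history_eda_ecg  = c(hist, "EDA", "ECG"),
       history_eda_ecg_bvp = c(hist, "EDA", "ECG", "BVP"),
       history_all_sensors = c(hist, "EDA", "ECG", "BVP", "EMG"))
}
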