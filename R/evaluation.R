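# Diagnostic evaluation: one-vs-rest confusion counts, sensitivity /
# specificity / F-measure / accuracy, type I-II error rates, the
# diagnostic odds ratio with its log-normal interval, rank-statistic
# AUC, and subject-stratified cross-validation.

#' One-vs-rest confusion counts per class
#'
#' @param true Character vector of true states.
#' @param predicted Character vector of predictions, same length.
#' @param classes Class order for the output (default N, A, E).
#' @return Data frame with one row per class and columns
#'   `class`, `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(true, predicted, classes = psych_states()) {
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  out <- lapply(classes, function(cl) {
    tp <- sum(true == cl & predicted == cl)
    fp <- sum(true != cl & predicted == cl)
    fn <- sum(true == cl & predicted != cl)
    tn <- sum(true != cl & predicted != cl)
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn)
  })
  do.call(rbind, out)
}

safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Per-class diagnostic rates
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, false positive
#' rate `FP/(FP+TN)`, false negative rate `FN/(FN+TP)`, F-measure
#' (harmonic mean of precision and sensitivity) and accuracy
#' `(TP+TN)/total`.  Zero denominators yield `NA` (flagged undefined),
#' never 0 or 1.
#'
#' @param counts Data frame from [confusion_counts()] (or a one-row
#'   subset).
#' @return The input with columns `Sen`, `Spe`, `FPR`, `FNR`, `FM`,
#'   `Acc` appended.
#' @export
diagnostic_rates <- function(counts) {
  with(counts, {
    sen <- safe_div(TP, TP + FN)
    spe <- safe_div(TN, TN + FP)
    prec <- safe_div(TP, TP + FP)
    fm <- ifelse(!is.na(prec) & !is.na(sen) & (prec + sen) > 0,
                 2 * prec * sen / (prec + sen), NA_real_)
    cbind(counts,
          Sen = sen, Spe = spe,
          FPR = safe_div(FP, FP + TN), FNR = safe_div(FN, FN + TP),
          FM = fm, Acc = (TP + TN) / (TP + FP + TN + FN))
  })
}

#' Diagnostic odds ratio with 95 percent confidence interval
#'
#' `DOR = (TP x TN) / (FP x FN)`; the interval uses the log-normal
#' method, `exp(ln DOR +/- 1.96 sqrt(1/TP + 1/FP + 1/TN + 1/FN))`.
#' When any cell is zero the Haldane 0.5 continuity correction is
#' applied and flagged.
#'
#' @param tp,fp,tn,fn Confusion cell counts (or pass a one-row counts
#'   data frame as `tp`).
#' @return List with `dor`, `ci` (length 2), `corrected`.
#' @examples
#' diagnostic_odds_ratio(21, 4, 26, 4)$dor  # 34.125
#' @export
diagnostic_odds_ratio <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    fp <- tp$FP; tn <- tp$TN; fn <- tp$FN; tp <- tp$TP
  }
  corrected <- any(c(tp, fp, tn, fn) == 0)
  if (corrected) {
    tp <- tp + 0.5; fp <- fp + 0.5; tn <- tn + 0.5; fn <- fn + 0.5
  }
  dor <- (tp * tn) / (fp * fn)
  se <- sqrt(1 / tp + 1 / fp + 1 / tn + 1 / fn)
  list(dor = dor, ci = exp(log(dor) + c(-1.96, 1.96) * se),
       corrected = corrected)
}

#' One-vs-rest AUC via the rank statistic
#'
#' Mann-Whitney formulation: for each class, the probability that a
#' positive window's score exceeds a negative's (ties count half).
#'
#' @param true Character vector of true classes.
#' @param scores Numeric matrix, one column per class (named), one row
#'   per window.
#' @return Named numeric vector of per-class AUCs (`NA` when a class
#'   has no positives or no negatives).
#' @export
roc_auc_ovr <- function(true, scores) {
  scores <- as.matrix(scores)
  vapply(colnames(scores), function(cl) {
    pos <- scores[true == cl, cl]
    neg <- scores[true != cl, cl]
    if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  }, numeric(1))
}

#' Full diagnostic report
#'
#' Per-class confusion counts, rates, diagnostic odds ratios with
#' intervals, optional AUCs, and macro averages (arithmetic means of
#' the per-class values).
#'
#' @param true,predicted State vectors of equal length.
#' @param scores Optional per-class score matrix for AUC.
#' @param classes Class order.
#' @return Object of class `psych_report`: a list with `per_class`
#'   (data frame) and `macro` (named vector).
#' @export
diagnostic_report <- function(true, predicted, scores = NULL,
                              classes = psych_states()) {
  tab <- diagnostic_rates(confusion_counts(true, predicted, classes))
  dor <- lapply(seq_len(nrow(tab)), function(i) diagnostic_odds_ratio(tab[i, ]))
  tab$DOR <- vapply(dor, `[[`, numeric(1), "dor")
  tab$DOR_lo <- vapply(dor, function(d) d$ci[1], numeric(1))
  tab$DOR_hi <- vapply(dor, function(d) d$ci[2], numeric(1))
  tab$DOR_corrected <- vapply(dor, `[[`, logical(1), "corrected")
  if (!is.null(scores)) tab$AUC <- roc_auc_ovr(true, scores)[tab$class]
  macro <- c(Sen = mean(tab$Sen, na.rm = TRUE),
             Spe = mean(tab$Spe, na.rm = TRUE),
             FPR = mean(tab$FPR, na.rm = TRUE),
             FNR = mean(tab$FNR, na.rm = TRUE),
             FM = mean(tab$FM, na.rm = TRUE),
             Acc = mean(true == predicted))
  if (!is.null(scores)) macro["AUC"] <- mean(tab$AUC, na.rm = TRUE)
  structure(list(per_class = tab, macro = macro,
                 n = length(true)), class = "psych_report")
}

#' @export
print.psych_report <- function(x, digits = 4, ...) {
  cat("Diagnostic report over", x$n, "predictions\n")
  tab <- x$per_class
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat("macro:", paste(names(x$macro), round(x$macro, digits), sep = "=",
                      collapse = " "), "\n")
  invisible(x)
}
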