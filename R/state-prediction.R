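# Window-level prediction from a decoded state sequence: three candidate
# extractors (longest run length, highest frequency count, most recent
# state) fused by majority vote.

severity_order <- function() c(N = 1, A = 2, E = 3)

#' Longest-run-length candidate state
#'
#' Scans the decoded sequence for maximal consecutive runs; the state
#' owning the longest run is the candidate.  Ties between equal-length
#' runs break toward the most recent run (recency mirrors the
#' most-recent-state extractor).
#'
#' @param q Character vector of decoded states (non-empty).
#' @return List with `state` and `run_length`, plus `runs` (the full
#'   run-length encoding) for audit.
#' @examples
#' longest_run_candidate(c("N","N","A","E","E","E","A","E","E","A"))
#' @export
longest_run_candidate <- function(q) {
  if (length(q) == 0) stop("decoded sequence is empty")
  r <- rle(as.character(q))
  best <- max(r$lengths)
  i <- max(which(r$lengths == best))  # most recent tied run wins
  list(state = r$values[i], run_length = best,
       runs = data.frame(state = r$values, length = r$lengths))
}

#' Highest-frequency-count candidate state
#'
#' Counts each state's occurrences over the whole sequence; the most
#' frequent state is the candidate.  Ties break toward the clinically
#' more severe state (E > A > N), preferring to flag an emergency.
#'
#' @inheritParams longest_run_candidate
#' @return List with `state`, `count`, and the per-state `counts`.
#' @export
highest_frequency_candidate <- function(q) {
  if (length(q) == 0) stop("decoded sequence is empty")
  q <- as.character(q)
  counts <- vapply(names(severity_order()), function(s) sum(q == s),
                   numeric(1))
  best <- max(counts)
  tied <- names(counts)[counts == best]
  state <- tied[which.max(severity_order()[tied])]
  list(state = state, count = as.integer(best), counts = counts)
}

#' Most recent state
#'
#' The state of the most recent time slot of the decoded sequence.
#'
#' @inheritParams longest_run_candidate
#' @return A single state label.
#' @export
most_recent_state <- function(q) {
  if (length(q) == 0) stop("decoded sequence is empty")
  as.character(q[length(q)])
}

#' Majority vote over the candidate ensemble
#'
#' Returns the candidate with the maximum multiplicity among the three
#' ensemble slots; a 1-1-1 tie resolves toward the most severe state
#' (E > A > N).
#'
#' @param ensemble Character vector of candidate states (length 3 in
#'   the standard pipeline).
#' @return List with `state`, `count` (winning multiplicity) and
#'   `votes` (the per-state tally).
#' @export
majority_vote <- function(ensemble) {
  ensemble <- as.character(ensemble)
  votes <- vapply(names(severity_order()), function(s) sum(ensemble == s),
                  numeric(1))
  best <- max(votes)
  tied <- names(votes)[votes == best]
  state <- tied[which.max(severity_order()[tied])]
  list(state = state, count = as.integer(best), votes = votes)
}

#' Predict the psychiatric state of one observation window
#'
#' Decodes the window with [viterbi_decode()], derives the three
#' candidates (longest run length, highest frequency count, most recent
#' state), forms the ensemble in that order and majority-votes it.  The
#' full audit trail — decoded sequence, every candidate, the tally and
#' the decoder log-probability — is retained in the result.
#'
#' @param params An [hmm_params()] object.
#' @param obs Observation sequence for the window (symbols or feature
#'   matrix, matching the emission model).
#' @param decoded Optionally, an already-decoded state sequence (the
#'   decoder is then skipped).
#' @return Object of class `psych_prediction`.
#' @export
predict_window <- function(params = NULL, obs = NULL, decoded = NULL) {
  logp <- NA_real_; flagged <- FALSE
  if (is.null(decoded)) {
    dec <- viterbi_decode(params, obs)
    decoded <- dec$path; logp <- dec$logp; flagged <- dec$flagged
  }
  lrl <- longest_run_candidate(decoded)
  hfc <- highest_frequency_candidate(decoded)
  mrs <- most_recent_state(decoded)
  ensemble <- c(lrl$state, hfc$state, mrs)
  mv <- majority_vote(ensemble)
  structure(list(decoded = decoded, lrl_candidate = lrl,
                 hfc_candidate = hfc, mrs_candidate = mrs,
                 ensemble = ensemble, predicted = mv$state,
                 vote_counts = mv$votes, winning_votes = mv$count,
                 logp = logp, flagged = flagged),
            class = "psych_prediction")
}

#' @export
print.psych_prediction <- function(x, ...) {
  cat("Window prediction:", x$predicted, "\n")
  cat("  decoded:", paste(x$decoded, collapse = ""), "\n")
  cat(sprintf("  LRL %s (run %d) | HFC %s (count %d) | MRS %s\n",
              x$lrl_candidate$state, x$lrl_candidate$run_length,
              x$hfc_candidate$state, x$hfc_candidate$count,
              x$mrs_candidate))
  cat("  votes:", paste(names(x$vote_counts), x$vote_counts, sep = ":",
                        collapse = " "), "\n")
  invisible(x)
}
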