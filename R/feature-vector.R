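# Fusion of the four sensor feature sets with rating-scale scores and
# history flags into one named feature vector per observation slot.

scale_group_map <- function() {
  c(BDI = "BDI", SSI = "SSI", BHS = "BHS", SCST = "SCST", BIS = "BIS",
    BPAQ = "BPAQ", BDHI = "BDHI", PHQ9 = "PHQ", GAD7 = "PHQ")
  # HRSD item 3 is deliberately absent: it defines the state labels and
  # would leak them into the observations.
}

history_group_map <- function() {
  c(family_suicide_history = "FH", medical_history = "MH",
    personal_trait = "PT")
}

#' Feature-name to provenance-group mapping
#'
#' Maps every feature the package extracts to its provenance group
#' (ECG, EDA, BVP, EMG, the rating scales, and the history flags MH, FH,
#' PT).
#'
#' @return Named character vector: names are feature names, values are
#'   group tags.
#' @export
feature_groups <- function() {
  sensor <- c(stats::setNames(rep("ECG", length(ecg_feature_names())),
                              ecg_feature_names()),
              stats::setNames(rep("EDA", length(eda_feature_names())),
                              eda_feature_names()),
              stats::setNames(rep("BVP", length(bvp_feature_names())),
                              bvp_feature_names()),
              stats::setNames(rep("EMG", length(emg_feature_names())),
                              emg_feature_names()))
  c(sensor, scale_group_map(), history_group_map())
}

#' Build the fused feature vector for one observation slot
#'
#' Extracts the four sensor feature sets from the slot's samples (each
#' channel is band-pass filtered over the slot first, so the vector is
#' strictly slot-local), then appends the subject's rating-scale scores
#' and 0/1-encoded history flags.  Missing channels or undetectable
#' fiducials yield explicitly flagged `NA` features, never silent zeros.
#'
#' @param recording A `psych_recording` (see [generate_cohort()]).
#' @param slot_index 1-based slot index.
#' @param band_edges Per-channel filter band edges (Hz); see
#'   [default_band_edges()] for the conventions.
#' @return List of class `feature_vector` with `slot_index`, `values`
#'   (named numeric) and `groups` (provenance tag per feature).
#' @export
build_feature_vector <- function(recording, slot_index,
                                 band_edges = default_band_edges()) {
  tau <- recording$tau
  bounds <- c((slot_index - 1) * tau, slot_index * tau)
  ch <- recording$channels
  fs <- recording$fs
  filt_feat <- function(name, fun) {
    if (is.null(ch[[name]])) return(flag_missing(get(paste0(name, "_feature_names"))()))
    be <- band_edges[[name]]
    x <- slice_slot(ch[[name]], fs[[name]], bounds)
    x <- bandpass_filter(x, fs[[name]], be[1], min(be[2], 0.49 * fs[[name]]))
    fun(x, fs[[name]])
  }
  vals <- c(filt_feat("ecg", ecg_features),
            filt_feat("eda", eda_features),
            filt_feat("bvp", bvp_features),
            filt_feat("emg", emg_features))
  sg <- scale_group_map()
  sc <- recording$scale_scores[names(sg)]
  names(sc) <- names(sg)
  hg <- history_group_map()
  hist <- as.numeric(recording$history[names(hg)])
  names(hist) <- names(hg)
  values <- c(vals, sc, hist)
  groups <- feature_groups()[names(values)]
  structure(list(slot_index = slot_index, values = values, groups = groups),
            class = "feature_vector")
}

#' Extract the feature table of a whole cohort
#'
#' One row per subject and slot: identifier columns (`subject`, `slot`,
#' `true_state`, `dominant`) followed by every fused feature.  The
#' feature-to-group mapping is kept in the `"groups"` attribute.
#'
#' @param cohort A `psych_cohort`.
#' @param band_edges Per-channel filter band edges.
#' @param verbose Print one progress line per subject.
#' @return A `data.frame` with attribute `groups`.
#' @export
cohort_features <- function(cohort, band_edges = default_band_edges(),
                            verbose = FALSE) {
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    if (verbose) message("features: ", rec$subject_id)
    n_slots <- length(rec$true_states)
    mat <- t(vapply(seq_len(n_slots), function(s)
      build_feature_vector(rec, s, band_edges)$values,
      numeric(length(feature_groups()))))
    rows[[i]] <- data.frame(subject = rec$subject_id,
                            slot = seq_len(n_slots),
                            true_state = rec$true_states,
                            dominant = rec$dominant,
                            mat, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- feature_groups()
  out
}

#' Column names of the feature table that are features
#'
#' @param features A feature table from [cohort_features()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("subject", "slot", "true_state", "dominant"))
}

#' Write / read a feature table
#'
#' CSV round trip of the [cohort_features()] table; the group attribute
#' is reconstructed from the feature names on read.
#'
#' @param features Feature table.
#' @param path CSV path.
#' @return `path` invisibly (write); the feature table (read).
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  attr(out, "groups") <- feature_groups()
  out
}
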