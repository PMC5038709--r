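# Per-sensor feature extraction.  Every extractor is slot-local: it sees
# only the samples inside the slot it is asked about, so downstream
# feature vectors cannot leak information across observation slots.

#' Conventional per-channel filter band edges
#'
#' ECG 0.5-40 Hz, BVP 0.5-8 Hz, EDA low-pass 1 Hz, EMG 20-450 Hz.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
default_band_edges <- function() {
  list(ecg = c(0.5, 40), bvp = c(0.5, 8), eda = c(0, 1), emg = c(20, 450))
}

#' Bazett rate-corrected QT interval
#'
#' @param qt QT interval in seconds.
#' @param rr Preceding R-R interval in seconds.
#' @return QTc = QT / sqrt(RR), in seconds.
#' @examples qtc_bazett(0.36, 0.81)  # 0.40
#' @export
qtc_bazett <- function(qt, rr) qt / sqrt(rr)

#' Detect R peaks in an ECG segment
#'
#' Derivative-squared energy detector (Pan-Tompkins style): the squared
#' first difference is integrated over a 150 ms window, regions above an
#' adaptive threshold are scanned for the local signal maximum, and a
#' 200 ms refractory period is enforced (keeping the larger peak on a
#' collision).
#'
#' @param ecg Filtered ECG sample vector.
#' @param fs Sampling rate in Hz.
#' @return Strictly increasing integer sample indices of R peaks; an
#'   (essentially) flat signal yields an empty vector.
#' @export
detect_r_peaks <- function(ecg, fs) {
  n <- length(ecg)
  if (n < 3) return(integer(0))
  energy <- centered_ma(c(0, diff(ecg))^2, round(0.15 * fs))
  if (max(energy) <= 1e-12) return(integer(0))
  above <- energy > 0.3 * max(energy)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- integer(0)
  for (j in which(r$values)) {
    seg <- starts[j]:ends[j]
    cand <- c(cand, seg[which.max(ecg[seg])])
  }
  enforce_refractory(cand, ecg, round(0.2 * fs))
}

# Greedy refractory pruning: peaks closer than `gap` samples collapse to
# the larger-amplitude one.
enforce_refractory <- function(cand, x, gap) {
  if (length(cand) == 0) return(integer(0))
  cand <- sort(cand)
  kept <- cand[1]
  for (i in cand[-1]) {
    last <- kept[length(kept)]
    if (i - last >= gap) kept <- c(kept, i)
    else if (x[i] > x[last]) kept[length(kept)] <- i
  }
  kept
}

# Local maxima above `frac` of the segment maximum, refractory `gap_s`.
detect_peaks_simple <- function(x, fs, frac = 0.6, gap_s = 0.4) {
  n <- length(x)
  if (n < 3 || max(x) - min(x) <= 1e-12) return(integer(0))
  loc <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  loc <- loc[x[loc] > min(x) + frac * (max(x) - min(x))]
  enforce_refractory(loc, x, round(gap_s * fs))
}

flag_missing <- function(names) stats::setNames(rep(NA_real_, length(names)),
                                                names)

ecg_feature_names <- function() {
  c("ecg_rr_mean", "ecg_rr_var", "ecg_rr_d1", "ecg_rr_d2",
    "ecg_qrs_amp", "ecg_qrs_dur", "ecg_qt", "ecg_qtc",
    "ecg_rs_ratio", "ecg_rpeak_amp", "ecg_rpeak_d1", "ecg_hr_bpm")
}

#' ECG features for one observation slot
#'
#' Beat-level fiducials (Q, R, S, T) are located around each detected R
#' peak; the slot is summarized by the mean/variance of the R-R series,
#' QRS amplitude and duration, QT and Bazett-corrected QTc intervals,
#' R/S ratio, R-peak amplitude, heart rate, and the means of the first
#' and second successive-difference series of the beat features.
#'
#' @param ecg Full ECG channel (or a slice).
#' @param fs Sampling rate in Hz.
#' @param slot_bounds Numeric `c(start_s, end_s)` of the slot within
#'   `ecg`; defaults to the whole vector.
#' @return Named numeric vector; all entries are `NA` (flagged missing)
#'   when fewer than two usable beats fall inside the slot.
#' @export
ecg_features <- function(ecg, fs, slot_bounds = NULL) {
  x <- slice_slot(ecg, fs, slot_bounds)
  nms <- ecg_feature_names()
  peaks <- detect_r_peaks(x, fs)
  # beats need fiducial context on both sides
  ctx_lo <- round(0.10 * fs); ctx_hi <- round(0.45 * fs)
  peaks <- peaks[peaks > ctx_lo & peaks <= length(x) - ctx_hi]
  if (length(peaks) < 2) return(flag_missing(nms))
  rr <- diff(peaks) / fs
  qi <- si <- ti <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    r <- peaks[k]
    wq <- max(1, r - round(0.08 * fs)):(r - round(0.01 * fs))
    ws <- (r + round(0.01 * fs)):min(length(x), r + round(0.08 * fs))
    wt <- (r + round(0.12 * fs)):min(length(x), r + round(0.42 * fs))
    qi[k] <- wq[which.min(x[wq])]
    si[k] <- ws[which.min(x[ws])]
    ti[k] <- wt[which.max(x[wt])]
  }
  qrs_amp <- x[peaks] - pmin(x[qi], x[si])
  qrs_dur <- (si - qi) / fs
  # QT from Q onset (12 ms before the Q trough) to T end (100 ms past
  # the T apex); QTc by Bazett using the preceding R-R interval
  qt <- (ti - qi) / fs + 0.112
  rr_prev <- c(rr[1], rr)
  qtc <- qtc_bazett(qt, rr_prev)
  rs_ratio <- abs(x[peaks]) / pmax(abs(x[si]), 1e-9)
  d1 <- function(v) if (length(v) >= 2) mean(diff(v)) else NA_real_
  d2 <- function(v) if (length(v) >= 3) mean(diff(v, differences = 2)) else NA_real_
  stats::setNames(c(mean(rr), stats::var(rr), d1(rr), d2(rr),
                    mean(qrs_amp), mean(qrs_dur), mean(qt), mean(qtc),
                    mean(rs_ratio), mean(x[peaks]), d1(x[peaks]),
                    60 / mean(rr)), nms)
}

eda_feature_names <- function() {
  c("eda_scl_mean", "eda_scr_count", "eda_scr_freq", "eda_scr_amp",
    "eda_scr_dur")
}

#' Electrodermal features for one observation slot
#'
#' Skin conductance responses are found by their characteristic rapid
#' rise: a sustained stretch where the smoothed conductance climbs
#' faster than `rise_rate` marks an SCR onset (slow tonic drift is an
#' order of magnitude slower); the response peak is the following local
#' maximum and the amplitude is measured trough-to-peak, kept when it
#' reaches `threshold`.  Events closer than 1 s merge.  Returns the
#' mean skin conductance level (tonic), SCR count, SCR frequency per
#' minute, mean SCR amplitude and mean SCR duration (half-amplitude
#' recovery width).  Amplitude and duration are flagged missing when
#' the slot has no SCR.
#'
#' @inheritParams ecg_features
#' @param eda EDA channel in microsiemens.
#' @param threshold Minimum SCR amplitude in microsiemens.
#' @param rise_rate Minimum onset slope in microsiemens per second.
#' @export
eda_features <- function(eda, fs, slot_bounds = NULL, threshold = 0.05,
                         rise_rate = 0.02) {
  x <- slice_slot(eda, fs, slot_bounds)
  n <- length(x)
  dur_s <- n / fs
  xs <- centered_ma(x, max(1, round(0.5 * fs)))
  k <- max(1, round(0.25 * fs))  # patch centered-MA zero edges
  if (n > 2 * k) {
    xs[seq_len(k)] <- xs[k + 1]
    xs[(n - k + 1):n] <- xs[n - k]
  }
  loc <- integer(0); amps <- numeric(0); troughs <- integer(0)
  if (n >= 5) {
    rising <- c(diff(xs), 0) * fs > rise_rate
    r <- rle(rising)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    min_run <- max(2L, round(0.2 * fs))
    for (j in which(r$values & r$lengths >= min_run)) {
      tmin <- starts[j]
      wp <- ends[j]:min(n, ends[j] + round(2 * fs))
      p <- wp[which.max(xs[wp])]
      a <- xs[p] - xs[tmin]
      if (a < threshold) next
      if (length(loc) > 0 && p - loc[length(loc)] < round(1 * fs)) next
      loc <- c(loc, p); amps <- c(amps, a); troughs <- c(troughs, tmin)
    }
  }
  count <- length(loc)
  amp <- dur <- NA_real_
  if (count > 0) {
    amp <- mean(amps)
    dur <- mean(vapply(seq_along(loc), function(j) {
      half <- xs[troughs[j]] + amps[j] / 2
      i0 <- loc[j]; while (i0 > troughs[j] && xs[i0] > half) i0 <- i0 - 1
      i1 <- loc[j]
      stop_at <- min(n, loc[j] + round(10 * fs))
      while (i1 < stop_at && xs[i1] > half) i1 <- i1 + 1
      (i1 - i0) / fs
    }, numeric(1)))
  }
  stats::setNames(c(mean(x), count, count / (dur_s / 60), amp, dur),
                  eda_feature_names())
}

bvp_feature_names <- function() {
  c("bvp_mm_mean", "bvp_mm_sd", "bvp_pulse_width", "bvp_pulse_area",
    "bvp_mq_mean", "bvp_pulse_interval", "bvp_sys_amp", "bvp_sys_amp_sd",
    "bvp_dia_amp", "bvp_aug_idx", "bvp_stiffness")
}

#' Blood-volume-pulse features for one observation slot
#'
#' Detects systolic peaks (M), the preceding systolic valley (S) and the
#' diastolic peak (Q) after the dicrotic notch, then summarizes M-M
#' interval (mean and sd), pulse width (half-amplitude), pulse area,
#' M-Q interval, foot-to-foot pulse interval, systolic and diastolic
#' amplitudes, augmentation index (diastolic / systolic amplitude) and a
#' stiffness index (nominal 1.75 m height over the M-Q delay).  Beats
#' with no detectable diastolic peak leave the Q-dependent features
#' flagged missing.
#'
#' @inheritParams ecg_features
#' @param bvp BVP channel.
#' @param height_m Nominal subject height for the stiffness index.
#' @export
bvp_features <- function(bvp, fs, slot_bounds = NULL, height_m = 1.75) {
  x <- slice_slot(bvp, fs, slot_bounds)
  nms <- bvp_feature_names()
  n <- length(x)
  m_pk <- detect_peaks_simple(x, fs, frac = 0.6, gap_s = 0.4)
  m_pk <- m_pk[m_pk > round(0.4 * fs) & m_pk <= n - round(0.55 * fs)]
  if (length(m_pk) < 2) return(flag_missing(nms))
  mm <- diff(m_pk) / fs
  feet <- q_amp <- q_dt <- width <- area <- sys_amp <- numeric(length(m_pk))
  q_ok <- logical(length(m_pk))
  for (k in seq_along(m_pk)) {
    m <- m_pk[k]
    wf <- max(1, m - round(0.4 * fs)):m
    f <- wf[which.min(x[wf])]            # systolic valley S (pulse foot)
    feet[k] <- f
    sys_amp[k] <- x[m] - x[f]
    wq <- (m + round(0.15 * fs)):min(n, m + round(0.55 * fs))
    # diastolic peak: an interior local maximum after the dicrotic notch
    ql <- wq[which(diff(sign(diff(x[wq]))) < 0) + 1L]
    if (length(ql) > 0) {
      q <- ql[which.max(x[ql])]
      q_ok[k] <- TRUE
      q_amp[k] <- x[q] - x[f]
      q_dt[k] <- (q - m) / fs
    }
    half <- x[f] + sys_amp[k] / 2
    i0 <- m; while (i0 > 1 && x[i0] > half) i0 <- i0 - 1
    i1 <- m; while (i1 < n && x[i1] > half) i1 <- i1 + 1
    width[k] <- (i1 - i0) / fs
    wa <- f:min(n, f + round(0.75 * fs))
    area[k] <- sum(pmax(x[wa] - x[f], 0)) / fs
  }
  mq <- if (any(q_ok)) mean(q_dt[q_ok]) else NA_real_
  dia <- if (any(q_ok)) mean(q_amp[q_ok]) else NA_real_
  aug <- if (any(q_ok)) dia / mean(sys_amp) else NA_real_
  stiff <- if (!is.na(mq) && mq > 0) height_m / mq else NA_real_
  stats::setNames(c(mean(mm), stats::sd(mm), mean(width), mean(area), mq,
                    mean(diff(feet)) / fs, mean(sys_amp),
                    stats::sd(sys_amp), dia, aug, stiff), nms)
}

emg_feature_names <- function() {
  c("emg_amp_mean", "emg_mean_freq", "emg_median_freq",
    "emg_gaps_per_min", "emg_gap_pct")
}

#' Surface-EMG features for one observation slot
#'
#' Mean rectified amplitude, mean and median frequency of the power
#' spectrum, the number of EMG gaps per minute and the percentage of
#' slot time spent in gaps.  A gap is a stretch where the 100 ms RMS
#' envelope stays below 10 percent of the slot RMS for at least 200 ms.
#'
#' @inheritParams ecg_features
#' @param emg EMG channel in mV.
#' @param gap_frac Envelope threshold as a fraction of slot RMS.
#' @param gap_min_s Minimum gap duration in seconds.
#' @export
emg_features <- function(emg, fs, slot_bounds = NULL, gap_frac = 0.1,
                         gap_min_s = 0.2) {
  x <- slice_slot(emg, fs, slot_bounds)
  n <- length(x)
  dur_s <- n / fs
  amp <- mean(abs(x))
  xd <- x - mean(x)
  spec <- Mod(stats::fft(xd))^2
  half <- seq_len(floor(n / 2))
  freqs <- (half - 1) * fs / n
  p <- spec[half]
  if (sum(p) <= 1e-24) {
    mean_f <- med_f <- NA_real_
  } else {
    mean_f <- sum(freqs * p) / sum(p)
    med_f <- freqs[which(cumsum(p) >= sum(p) / 2)[1]]
  }
  env <- sqrt(pmax(centered_ma(x^2, round(0.1 * fs)), 0))
  rms <- sqrt(mean(x^2))
  below <- env < gap_frac * rms
  r <- rle(below)
  gap_runs <- r$values & r$lengths >= round(gap_min_s * fs)
  n_gaps <- sum(gap_runs)
  gap_time <- sum(r$lengths[gap_runs]) / fs
  stats::setNames(c(amp, mean_f, med_f, n_gaps / (dur_s / 60),
                    100 * gap_time / dur_s), emg_feature_names())
}

slice_slot <- function(x, fs, slot_bounds) {
  if (is.null(slot_bounds)) return(x)
  i0 <- floor(slot_bounds[1] * fs) + 1L
  i1 <- min(length(x), round(slot_bounds[2] * fs))
  if (i0 > i1) stop("empty slot bounds")
  x[i0:i1]
}
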