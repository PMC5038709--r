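#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward (zero phase lag),
#' removing baseline wander below `low` and high-frequency noise above
#' `high`.  A `low` of 0 degenerates to a pure low-pass.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param low Lower band edge in Hz (`0 <= low < high`).
#' @param high Upper band edge in Hz (`high < fs/2`).
#' @param order Butterworth order (default 6: about 4 percent stop-band
#'   leakage one octave-fifth past the edge, stable for all channel bands).
#' @return Filtered signal, same length as `x`.
#' @examples
#' fs <- 250; t <- seq(0, 2, by = 1/fs)
#' x <- sin(2 * pi * 10 * t) + 0.5            # 10 Hz tone on a DC offset
#' y <- bandpass_filter(x, fs, 0.5, 40)       # offset removed, tone kept
#' @export
bandpass_filter <- function(x, fs, low, high, order = 6) {
  if (!(low >= 0 && low < high && high < fs / 2))
    stop("invalid band edges: need 0 <= low < high < fs/2")
  bf <- if (low <= 0) signal::butter(order, high / (fs / 2), type = "low")
        else signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # mean-center before filtering to tame start/end transients; a pure
  # low-pass passes DC, so restore the mean afterwards
  xm <- mean(x)
  y <- as.numeric(signal::filtfilt(bf, x - xm))
  if (low <= 0) y + xm else y
}

#' Trailing moving average
#'
#' Smooths a signal with a trailing window of `window` samples; near the
#' start the effective window is truncated to the samples available, so
#' the output has the same length as the input and a constant signal is
#' left unchanged.
#'
#' @param x Numeric sample vector.
#' @param window Window length in samples (>= 1, <= `length(x)`);
#'   the conventional smoothing window for these biosignals is 15.
#' @return Smoothed signal of the same length.
#' @examples
#' moving_average(1:30, 15)[15]  # mean(1:15) = 8
#' @export
moving_average <- function(x, window = 15) {
  n <- length(x)
  window <- as.integer(window)
  if (window < 1 || window > n) stop("window must be in [1, length(x)]")
  if (window == 1) return(x)
  cs <- cumsum(x)
  out <- numeric(n)
  head_idx <- seq_len(window - 1)
  out[head_idx] <- cs[head_idx] / head_idx
  idx <- window:n
  out[idx] <- (cs[idx] - c(0, cs)[idx - window + 1]) / window
  out
}

# Centered moving average used internally by the peak detectors (edge
# samples fall back to the trailing version's truncation behaviour).
centered_ma <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window == 1) return(x)
  y <- stats::filter(x, rep(1 / window, window), sides = 2)
  y <- as.numeric(y)
  y[is.na(y)] <- 0
  y
}
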