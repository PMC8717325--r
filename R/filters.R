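#' Zero-phase high-pass filter
#'
#' Removes low-frequency rumble from call recordings with a 4th-order
#' Butterworth filter run forward and backward (`signal::filtfilt`), so the
#' temporal landmarks used downstream (onset, time to maximum amplitude) are
#' not shifted by filter group delay.
#'
#' @param wave A [waveform].
#' @param cutoff Cutoff frequency in Hz (default 200); must lie below the
#'   Nyquist frequency.
#' @param order Filter order (default 4).
#' @return The filtered [waveform].
#' @export
highpass <- function(wave, cutoff = 200, order = 4) {
  assert_waveform(wave)
  if (!is.numeric(cutoff) || cutoff <= 0) {
    stop("cutoff must be a positive frequency in Hz", call. = FALSE)
  }
  if (cutoff >= wave$sample_rate / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (wave$sample_rate / 2), type = "high")
  waveform(signal::filtfilt(bf, wave$samples), wave$sample_rate)
}

# Analytic-signal magnitude via the FFT: zero the negative frequencies,
# double the positive ones. Exact for narrowband signals away from edges.
analytic_envelope <- function(x) Mod(analytic_signal(x))

# Centered moving average with shrinking windows at the edges, so the first
# and last samples keep their own (locally averaged) level.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  n <- length(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smoothed amplitude envelope of a waveform
#'
#' Magnitude of the analytic signal, smoothed with a centered moving average.
#'
#' @param wave A [waveform].
#' @param smooth_ms Smoothing window in ms (default 2).
#' @return Numeric vector of envelope values, one per sample.
#' @export
amplitude_envelope <- function(wave, smooth_ms = 2) {
  assert_waveform(wave)
  env <- analytic_envelope(wave$samples)
  moving_average(env, round(smooth_ms / 1000 * wave$sample_rate))
}

# Hamming window (periodic-agnostic symmetric form, as used for spectrograms)
hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Next power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(n))
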