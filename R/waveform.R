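#' Sampled waveform
#'
#' The universal currency between all stages of the pipeline: a real-valued
#' sampled signal together with its sample rate. Audio recordings use
#' 44.1 kHz; laser-vibrometer traces use 200 kHz.
#'
#' @param samples Numeric vector of finite sample values. For audio export
#'   the absolute value must not exceed 1 (full scale).
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `waveform`: a list with elements `samples`
#'   and `sample_rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration_s(w)
#' @export
waveform <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("waveform must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("waveform samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.1f ms), peak %.4g>\n",
              length(x$samples), x$sample_rate,
              1000 * length(x$samples) / x$sample_rate,
              max(abs(x$samples))))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

#' @export
plot.waveform <- function(x, ...) {
  t_ms <- (seq_along(x$samples) - 1) / x$sample_rate * 1000
  graphics::plot(t_ms, x$samples, type = "l",
                 xlab = "Time (ms)", ylab = "Amplitude", ...)
  invisible(x)
}

is_waveform <- function(x) inherits(x, "waveform")

assert_waveform <- function(x, arg = deparse(substitute(x))) {
  if (!is_waveform(x)) stop(sprintf("`%s` must be a waveform", arg), call. = FALSE)
  invisible(x)
}

#' Waveform duration in seconds
#' @param wave A [waveform].
#' @return Duration in seconds.
#' @export
duration_s <- function(wave) {
  assert_waveform(wave)
  length(wave$samples) / wave$sample_rate
}

#' Root-mean-square amplitude
#' @param x A [waveform] or numeric vector.
#' @return The RMS value.
#' @export
rms <- function(x) {
  if (is_waveform(x)) x <- x$samples
  sqrt(mean(x^2))
}

#' Run configuration
#'
#' Bundles the sampling rates, filter cutoff, seed and output directory that
#' are shared across pipeline stages.
#'
#' @param sample_rate_audio Audio sampling rate in Hz (default 44100).
#' @param sample_rate_vibro Vibrometer acquisition rate in Hz (default 200000).
#' @param highpass_cutoff High-pass cutoff in Hz applied to call recordings
#'   (default 200).
#' @param rng_seed Integer seed fixed for the run.
#' @param output_dir Output directory for tables and metadata.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sample_rate_audio = 44100,
                       sample_rate_vibro = 200000,
                       highpass_cutoff = 200,
                       rng_seed = 1L,
                       output_dir = tempdir()) {
  if (highpass_cutoff >= sample_rate_audio / 2) {
    stop("highpass_cutoff must be below the audio Nyquist frequency", call. = FALSE)
  }
  structure(list(sample_rate_audio = sample_rate_audio,
                 sample_rate_vibro = sample_rate_vibro,
                 highpass_cutoff = highpass_cutoff,
                 rng_seed = as.integer(rng_seed),
                 output_dir = output_dir),
            class = "run_config")
}

#' FFT bin spacing
#'
#' Frequency resolution of an `n_fft`-point transform at a given sample rate;
#' 8192 points at 200 kHz gives 24.41 Hz, 2048 points gives 97.66 Hz.
#'
#' @param sample_rate Sampling rate in Hz.
#' @param n_fft Transform length in points.
#' @return Bin spacing in Hz.
#' @export
fft_resolution <- function(sample_rate, n_fft) sample_rate / n_fft
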