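#' Parameters of a synthetic harmonic distress call
#'
#' Describes a harmonic call with a linear downward (or upward) sweep of the
#' fundamental, a fixed number of harmonics with a per-harmonic amplitude
#' roll-off, and an amplitude envelope peaking at `time_to_max_ms`.
#'
#' @param n_harmonics Number of harmonics (>= 1).
#' @param duration_ms Call duration in ms.
#' @param time_to_max_ms Time from call onset to the envelope maximum, in ms;
#'   must lie strictly inside the call.
#' @param f0_start_hz Fundamental frequency at call onset, Hz.
#' @param f0_end_hz Fundamental frequency at call offset, Hz.
#' @param harmonic_rolloff_db Attenuation per harmonic index in dB (harmonic
#'   `k` is attenuated by `(k - 1) * harmonic_rolloff_db`). The default of
#'   6 dB keeps the fundamental as the dominant frequency.
#' @param sample_rate_hz Sampling rate, Hz (default 44100).
#' @return A list of class `call_params`.
#' @seealso [population_call_params()] for the two population parameter sets.
#' @export
call_params <- function(n_harmonics,
                        duration_ms,
                        time_to_max_ms,
                        f0_start_hz,
                        f0_end_hz = f0_start_hz,
                        harmonic_rolloff_db = 6,
                        sample_rate_hz = 44100) {
  if (n_harmonics < 1) stop("n_harmonics must be >= 1", call. = FALSE)
  if (!(time_to_max_ms > 0 && time_to_max_ms < duration_ms)) {
    stop("time_to_max_ms must lie strictly between 0 and duration_ms",
         call. = FALSE)
  }
  if (n_harmonics * max(f0_start_hz, f0_end_hz) >= sample_rate_hz / 2) {
    stop("highest harmonic reaches the Nyquist frequency (aliasing)",
         call. = FALSE)
  }
  structure(list(n_harmonics = as.integer(n_harmonics),
                 duration_ms = duration_ms,
                 time_to_max_ms = time_to_max_ms,
                 f0_start_hz = f0_start_hz,
                 f0_end_hz = f0_end_hz,
                 harmonic_rolloff_db = harmonic_rolloff_db,
                 sample_rate_hz = sample_rate_hz),
            class = "call_params")
}

#' Population-average synthetic call parameters
#'
#' The two parameter sets used as playback stimuli: the central-population
#' call (six harmonics, 71 ms, maximum amplitude at 26 ms, fundamental
#' sweeping down from 2.7 to 2.1 kHz) and the southern-population call
#' (three harmonics, 42 ms, maximum at 19 ms, 6.3 sweeping down to 5.6 kHz).
#' In both calls the fundamental is also the dominant frequency.
#'
#' @param population `"central"` or `"southern"`.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return A [call_params] object.
#' @export
population_call_params <- function(population = c("central", "southern"),
                                   sample_rate_hz = 44100) {
  population <- match.arg(population)
  switch(population,
    central = call_params(n_harmonics = 6, duration_ms = 71,
                          time_to_max_ms = 26, f0_start_hz = 2700,
                          f0_end_hz = 2100, sample_rate_hz = sample_rate_hz),
    southern = call_params(n_harmonics = 3, duration_ms = 42,
                           time_to_max_ms = 19, f0_start_hz = 6300,
                           f0_end_hz = 5600, sample_rate_hz = sample_rate_hz)
  )
}

# Amplitude envelope anchored at the -20 dB measurement floor: a raised-cosine
# attack whose first sample sits exactly at `floor` and whose peak falls at
# time_to_max, followed by an exponential decay that returns to `floor` at the
# nominal offset. The -20 dB onset/offset crossings used by the feature
# extractor therefore coincide with the nominal duration and time-to-max.
call_envelope <- function(n, sample_rate, duration_ms, time_to_max_ms,
                          floor = 0.1) {
  t_ms <- (seq_len(n) - 1) / sample_rate * 1000
  x0 <- acos(1 - 2 * floor) / pi              # raised-cosine phase at `floor`
  delta <- time_to_max_ms * x0 / (1 - x0)
  env <- numeric(n)
  attack <- t_ms <= time_to_max_ms
  env[attack] <- 0.5 * (1 - cos(pi * (t_ms[attack] + delta) /
                                  (time_to_max_ms + delta)))
  lambda <- -log(floor) / (duration_ms - time_to_max_ms)
  env[!attack] <- exp(-lambda * (t_ms[!attack] - time_to_max_ms))
  env
}

#' Synthesize a harmonic call
#'
#' Builds a phase-coherent harmonic stack whose fundamental sweeps linearly
#' from `f0_start_hz` to `f0_end_hz` over the call duration; harmonic `k`
#' tracks `k` times the instantaneous fundamental and is attenuated by
#' `(k - 1) * harmonic_rolloff_db` dB. The amplitude envelope rises to its
#' peak at `time_to_max_ms` and decays exponentially afterwards.
#'
#' @param params A [call_params] object.
#' @param peak Peak output amplitude after normalization (default 0.9).
#' @return A [waveform] at `params$sample_rate_hz`.
#' @export
synthesize_harmonic_call <- function(params, peak = 0.9) {
  stopifnot(inherits(params, "call_params"))
  sr <- params$sample_rate_hz
  n <- round(params$duration_ms / 1000 * sr)
  t <- (seq_len(n) - 1) / sr
  dur_s <- params$duration_ms / 1000
  sweep_rate <- (params$f0_end_hz - params$f0_start_hz) / dur_s
  # integral of the instantaneous fundamental
  phase0 <- 2 * pi * (params$f0_start_hz * t + 0.5 * sweep_rate * t^2)
  x <- numeric(n)
  for (k in seq_len(params$n_harmonics)) {
    a_k <- 10^(-(k - 1) * params$harmonic_rolloff_db / 20)
    x <- x + a_k * sin(k * phase0)
  }
  env <- call_envelope(n, sr, params$duration_ms, params$time_to_max_ms)
  x <- x * env
  waveform(x / max(abs(x)) * peak, sr)
}

#' Synthesize a noisy (non-harmonic) call
#'
#' Band-limited Gaussian noise shaped with the same amplitude-envelope model
#' as harmonic calls; emulates the turbulent, non-harmonic distress calls.
#'
#' @param duration_ms Call duration, ms.
#' @param band_low_hz,band_high_hz Passband edges, Hz; must satisfy
#'   `0 < band_low_hz < band_high_hz < sample_rate_hz / 2`.
#' @param time_to_max_ms Time to the envelope maximum, ms.
#' @param seed Integer seed; fixed seeds give bit-identical output.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param peak Peak amplitude after normalization.
#' @return A [waveform].
#' @export
synthesize_noisy_call <- function(duration_ms, band_low_hz, band_high_hz,
                                  time_to_max_ms, seed = 1L,
                                  sample_rate_hz = 44100, peak = 0.9) {
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz &&
        band_high_hz < sample_rate_hz / 2)) {
    stop("noise band must satisfy 0 < low < high < Nyquist", call. = FALSE)
  }
  n <- round(duration_ms / 1000 * sample_rate_hz)
  x <- with_seed(seed, stats::rnorm(n))
  bf <- signal::butter(4, c(band_low_hz, band_high_hz) / (sample_rate_hz / 2),
                       type = "pass")
  x <- signal::filtfilt(bf, x)
  env <- call_envelope(n, sample_rate_hz, duration_ms, time_to_max_ms)
  # flatten the noise's own fluctuating envelope so the imposed amplitude
  # envelope (and hence the measured duration) is followed tightly
  own_env <- moving_average(analytic_envelope(x), round(0.001 * sample_rate_hz))
  x <- x / pmax(own_env, 1e-12 * max(own_env)) * env
  waveform(x / max(abs(x)) * peak, sample_rate_hz)
}

#' Pure-tone stimulus schedule
#'
#' Enumerates the stimulus frequencies used for tympanic recordings: 0.1 kHz,
#' then 0.2 to 9.0 kHz in 0.2-kHz steps, 9.5 to 20 kHz in 0.5-kHz steps and
#' 22 to 40 kHz in 2-kHz steps (78 frequencies in total), crossed with the
#' requested sound pressure levels. Each tone lasts `duration_ms` with linear
#' rise/fall ramps and is followed by a silence of the same duration.
#'
#' @param spl_levels Sound pressure levels in dB SPL
#'   (default `c(55, 60, 70, 80)`).
#' @param duration_ms Tone duration, ms (default 100).
#' @param ramp_ms Rise and fall ramp, ms (default 10).
#' @param counterbalance_seed Optional integer; when given, rows are returned
#'   in a seeded random presentation order instead of sorted order.
#' @return A data frame of class `tone_schedule` with columns
#'   `frequency_hz`, `level_db_spl`, `duration_ms`, `ramp_ms`, `silence_ms`.
#' @export
make_tone_schedule <- function(spl_levels = c(55, 60, 70, 80),
                               duration_ms = 100, ramp_ms = 10,
                               counterbalance_seed = NULL) {
  if (length(spl_levels) < 1) stop("spl_levels must be non-empty", call. = FALSE)
  freqs <- schedule_frequencies()
  out <- expand.grid(frequency_hz = freqs, level_db_spl = spl_levels,
                     KEEP.OUT.ATTRS = FALSE)
  out$duration_ms <- duration_ms
  out$ramp_ms <- ramp_ms
  out$silence_ms <- duration_ms
  if (!is.null(counterbalance_seed)) {
    out <- out[with_seed(counterbalance_seed, sample.int(nrow(out))), ]
    rownames(out) <- NULL
  }
  class(out) <- c("tone_schedule", "data.frame")
  out
}

# The three arithmetic progressions plus the 0.1 kHz starting tone. The
# 0.5-kHz-step range starts at 9.5 kHz and the 2-kHz-step range at 22 kHz so
# that no frequency is duplicated at the range joints.
schedule_frequencies <- function() {
  1000 * c(0.1,
           round(seq(0.2, 9.0, by = 0.2), 1),
           round(seq(9.5, 20, by = 0.5), 1),
           seq(22, 40, by = 2))
}

#' Synthesize a pure-tone stimulus
#'
#' A tone of `duration_ms` with linear on/off ramps, followed by a silence of
#' `silence_ms`. Digital amplitude encodes the sound pressure level relative
#' to a declared reference (`reference_db` dB SPL corresponds to full scale),
#' so a 20 dB SPL increase multiplies the amplitude by 10.
#'
#' @param stim A single row of a [make_tone_schedule()] data frame, or a list
#'   with fields `frequency_hz`, `level_db_spl`, `duration_ms`, `ramp_ms`,
#'   `silence_ms`.
#' @param sample_rate Sampling rate, Hz (default 200000, the vibrometry
#'   acquisition rate).
#' @param reference_db SPL mapped to unit amplitude (default 94).
#' @return A [waveform] of length `(duration_ms + silence_ms) * sample_rate`.
#' @export
synthesize_tone <- function(stim, sample_rate = 200000, reference_db = 94) {
  stim <- as.list(stim)
  f <- stim$frequency_hz
  if (f >= sample_rate / 2) {
    stop("tone frequency must be below the Nyquist frequency", call. = FALSE)
  }
  if (stim$ramp_ms > stim$duration_ms / 2) {
    stop("ramps must fit inside the tone", call. = FALSE)
  }
  n_tone <- round(stim$duration_ms / 1000 * sample_rate)
  n_sil <- round(stim$silence_ms / 1000 * sample_rate)
  t <- (seq_len(n_tone) - 1) / sample_rate
  amp <- 10^((stim$level_db_spl - reference_db) / 20)
  x <- amp * sin(2 * pi * f * t)
  n_ramp <- round(stim$ramp_ms / 1000 * sample_rate)
  if (n_ramp > 0) {
    ramp <- seq(0, 1, length.out = n_ramp)
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
    x[(n_tone - n_ramp + 1):n_tone] <- x[(n_tone - n_ramp + 1):n_tone] * rev(ramp)
  }
  waveform(c(x, numeric(n_sil)), sample_rate)
}

#' Insert a nonlinear-phenomenon segment into a call
#'
#' Modifies a segment of a call to emulate the irregularities seen in complex
#' distress calls: subharmonics (added energy at half the fundamental),
#' frequency jumps (a discontinuous shift of the harmonic stack), deterministic
#' chaos (replacement with amplitude-modulated broadband noise; a fixture, not
#' a simulation of chaotic dynamics) or a silence gap. Samples outside the
#' segment are untouched.
#'
#' @param wave A [waveform].
#' @param kind One of `"subharmonic"`, `"frequency_jump"`,
#'   `"deterministic_chaos"`, `"silence_gap"`.
#' @param start_ms Segment start, ms from the beginning of the waveform.
#' @param len_ms Segment length, ms.
#' @param f0_hz Local fundamental frequency, Hz (used by the subharmonic and
#'   frequency-jump kinds).
#' @param jump_fraction Relative fundamental shift for `"frequency_jump"`
#'   (default 0.3, i.e. the stack jumps up by 30%).
#' @param seed Seed for the `"deterministic_chaos"` noise.
#' @return The modified [waveform].
#' @export
insert_nonlinearity <- function(wave,
                                kind = c("subharmonic", "frequency_jump",
                                         "deterministic_chaos", "silence_gap"),
                                start_ms, len_ms, f0_hz = NULL,
                                jump_fraction = 0.3, seed = 1L) {
  assert_waveform(wave)
  kind <- match.arg(kind)
  sr <- wave$sample_rate
  i0 <- round(start_ms / 1000 * sr) + 1
  i1 <- i0 + round(len_ms / 1000 * sr) - 1
  if (i0 < 1 || i1 > length(wave$samples) || i1 < i0) {
    stop("nonlinearity segment lies outside the waveform", call. = FALSE)
  }
  idx <- i0:i1
  seg <- wave$samples[idx]
  n <- length(seg)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann

  out <- wave$samples
  out[idx] <- switch(kind,
    silence_gap = 0,
    subharmonic = {
      if (is.null(f0_hz)) stop("f0_hz required for subharmonic", call. = FALSE)
      t <- (idx - 1) / sr
      seg + sqrt(2) * rms(seg) * sin(2 * pi * (f0_hz / 2) * t) * taper
    },
    frequency_jump = {
      if (is.null(f0_hz)) stop("f0_hz required for frequency_jump", call. = FALSE)
      # single-sideband shift of the whole stack by jump_fraction * f0
      analytic <- analytic_signal(seg)
      t <- (seq_len(n) - 1) / sr
      shifted <- Re(analytic * exp(2i * pi * jump_fraction * f0_hz * t))
      seg * (1 - taper) + shifted * taper
    },
    deterministic_chaos = {
      noise <- with_seed(seed, stats::rnorm(n))
      bf <- signal::butter(4, c(0.02, 0.6))
      noise <- signal::filtfilt(bf, noise)
      am <- 1 + 0.5 * sin(2 * pi * 37 * (seq_len(n) - 1) / sr)
      noise <- noise * am
      noise * (rms(seg) / rms(noise)) * taper
    }
  )
  waveform(out, sr)
}

# Complex analytic signal (positive-frequency part doubled)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
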