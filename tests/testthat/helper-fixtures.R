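# Shared fixtures, memoized so expensive synthesis runs once per suite.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, expr, envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

central_call <- function() {
  memo("central", synthesize_harmonic_call(population_call_params("central")))
}

southern_call <- function() {
  memo("southern", synthesize_harmonic_call(population_call_params("southern")))
}

# Calls resampled to the vibrometry rate, zero-padded to at least one
# analysis window, as used for call-response matching.
call_spectrum_200k <- function(pop) {
  memo(paste0("callspec_", pop), {
    w <- if (pop == "central") central_call() else southern_call()
    n_out <- round(length(w$samples) * 200000 / w$sample_rate)
    x <- stats::approx(seq_along(w$samples), w$samples, n = n_out)$y
    if (length(x) < 2048) x <- c(x, numeric(2048 - length(x)))
    power_spectrum(waveform(x, 200000), n_fft = 2048, overlap = 0.5)
  })
}

# Trace-unit conversion used by the simulator defaults (5 mm/s per volt,
# 20 dB gain): digital units per m/s.
UNITS_PER_M_S <- 10^(20 / 20) / 0.005

# Noise level corresponding to 10% of the stimulus-window RMS of the
# response at the center frequency, for a given peak velocity in m/s.
noise_sd_10pct <- function(peak_velocity_m_s) {
  0.1 * peak_velocity_m_s * UNITS_PER_M_S / sqrt(2)
}

# A deterministic synthetic sinusoidal "velocity trace" (tone + silence) of
# known velocity amplitude, in digital trace units.
sine_trace <- function(freq_hz, velocity_m_s, sample_rate = 200000,
                       duration_ms = 100, silence_ms = 100) {
  n_tone <- round(duration_ms / 1000 * sample_rate)
  n_sil <- round(silence_ms / 1000 * sample_rate)
  amp <- velocity_m_s * UNITS_PER_M_S
  t <- (seq_len(n_tone) - 1) / sample_rate
  waveform(c(amp * sin(2 * pi * freq_hz * t), numeric(n_sil)), sample_rate)
}

# Random call parameters inside the printed population ranges, respecting
# the aliasing constraint on the highest harmonic.
random_call_params <- function() {
  f0 <- stats::runif(1, 2700, 6300)
  n_max <- min(6L, floor(21000 / f0))
  n <- sample(3:n_max, 1)
  dur <- stats::runif(1, 42, 71)
  ttm <- stats::runif(1, 19, min(26, dur - 5))
  call_params(n_harmonics = n, duration_ms = dur, time_to_max_ms = ttm,
              f0_start_hz = f0, f0_end_hz = f0 - stats::runif(1, 600, 700))
}
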