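stim_1k <- function() {
  s <- make_tone_schedule(80)[6, ]   # 1.0 kHz row
  stopifnot(s$frequency_hz == 1000)
  s
}

test_that("replicate SNR uses centered 80-ms windows and scales correctly", {
  sr <- 200000
  stim <- stim_1k()

  # tone of amplitude A against a silence of tiny known RMS
  A <- 0.3
  eps <- 1e-4
  t <- (0:19999) / sr
  trace <- waveform(c(A * sin(2 * pi * 1000 * t),
                      eps * rep_len(c(1, -1), 20000)), sr)
  snr <- replicate_snr(trace, stim)
  expect_equal(snr$ratio, (A / sqrt(2)) / eps, tolerance = 0.01)

  # identical stimulus and silence content gives ratio 1
  same <- waveform(rep(sin(2 * pi * 1000 * t), 2), sr)
  expect_equal(replicate_snr(same, stim)$ratio, 1, tolerance = 1e-9)

  # global scaling leaves the ratio unchanged
  scaled <- waveform(5 * trace$samples, sr)
  expect_equal(replicate_snr(scaled, stim)$ratio, snr$ratio, tolerance = 1e-12)

  expect_error(replicate_snr(waveform(numeric(100), sr), stim), "shorter")
})

test_that("quartile filtering drops the floor(n/4) lowest-SNR replicates", {
  sr <- 200000
  stim <- stim_1k()
  base <- synthesize_tone(stim, sr)$samples

  # ranks known by construction: replicate k gets noise sd proportional to k
  traces <- lapply(1:20, function(k) {
    set.seed(k)
    waveform(base + stats::rnorm(length(base), sd = 2e-4 * k), sr)
  })
  reps <- replicate_set(traces, stim)
  avg <- filter_and_average(reps)
  expect_identical(attr(avg, "n_used"), 15L)
  # the five noisiest (lowest-SNR) replicates are the ones discarded
  expect_identical(sort(attr(avg, "kept")), 1:15)

  # deterministic under exact ties, broken by replicate order
  tied <- replicate_set(lapply(1:8, function(k) waveform(base, sr)), stim)
  a1 <- filter_and_average(tied)
  a2 <- filter_and_average(tied)
  expect_identical(attr(a1, "kept"), attr(a2, "kept"))
  expect_identical(attr(a1, "kept"), 3:8)   # first two (quartile) dropped

  expect_error(
    filter_and_average(replicate_set(traces[1:3], stim)),
    "at least 4")
})

test_that("averaging the retained replicates improves SNR by about sqrt(15)", {
  sr <- 10000
  stim <- list(frequency_hz = 500, level_db_spl = 80, duration_ms = 100,
               ramp_ms = 10, silence_ms = 100)
  t <- (0:999) / sr
  base <- c(0.5 * sin(2 * pi * 500 * t), numeric(1000))
  set.seed(77)
  gains <- replicate(100, {
    traces <- lapply(1:20, function(k)
      waveform(base + stats::rnorm(2000, sd = 0.05), sr))
    avg <- filter_and_average(replicate_set(traces, stim))
    resid_avg <- stats::sd(avg$samples - base)
    0.05 / resid_avg
  })
  expect_equal(mean(gains), sqrt(15), tolerance = 0.1)
})

test_that("velocity readout recovers known sinusoid amplitudes within 2%", {
  # on-grid and off-grid frequencies, including the documented 4 kHz case
  for (freq in c(4000, 4321, 1000, 8300)) {
    v_true <- 2e-3
    tr <- sine_trace(freq, v_true)
    expect_equal(velocity_at_frequency(tr, freq), v_true,
                 tolerance = 0.02)
  }

  expect_equal(velocity_at_frequency(
    waveform(numeric(40000), 200000), 4000), 0)

  # velocity is linear in trace amplitude
  tr <- sine_trace(4000, 1e-3)
  tr2 <- waveform(2 * tr$samples, 200000)
  expect_equal(velocity_at_frequency(tr2, 4000),
               2 * velocity_at_frequency(tr, 4000), tolerance = 1e-9)

  expect_error(velocity_at_frequency(tr, 150000), "Nyquist")
  expect_error(velocity_at_frequency(waveform(numeric(5000), 200000), 1000),
               "shorter")
})

test_that("the velocity grid spacing matches the printed resolutions", {
  expect_equal(fft_resolution(200000, 8192), 24.41, tolerance = 0.001)
  expect_equal(fft_resolution(200000, 2048), 97.66, tolerance = 0.001)
})

test_that("transfer functions are ordered, gap-preserving and duplicate-free", {
  df <- data.frame(frequency_hz = c(3000, 1000, 2000),
                   velocity_m_s = c(3, 1, 2) * 1e-4)
  tf <- build_transfer_function(df, spl = 80)
  expect_identical(tf$frequency_hz, c(1000, 2000, 3000))
  expect_identical(attr(tf, "spl"), 80)

  # a missing frequency stays missing: rows are whatever was measured
  expect_identical(nrow(tf), 3L)

  dup <- data.frame(frequency_hz = c(1000, 1000), velocity_m_s = c(1, 2))
  expect_error(build_transfer_function(dup), "duplicate")

  # a flat simulated eardrum yields a flat transfer function
  sched <- make_tone_schedule(80)
  sched <- sched[sched$frequency_hz <= 8000, ]
  flat <- eardrum_model(NA, noise_sd = 0)
  vels <- vapply(seq_len(nrow(sched)), function(s) {
    reps <- simulate_tone_replicates(flat, sched[s, ], n_reps = 4, seed = s)
    velocity_at_frequency(filter_and_average(reps), sched$frequency_hz[s])
  }, numeric(1))
  expect_lt(diff(range(vels)) / mean(vels), 0.05)

  # the full 78-tone schedule yields a 78-point transfer function
  full <- build_transfer_function(
    data.frame(frequency_hz = make_tone_schedule(80)$frequency_hz,
               velocity_m_s = seq_len(78) * 1e-5))
  expect_identical(nrow(full), 78L)
})

test_that("tympanic summaries interpolate half-max limits and handle edges", {
  tri <- build_transfer_function(
    data.frame(frequency_hz = c(3000, 4500, 6000, 7000, 8000),
               velocity_m_s = c(0.25, 0.5, 1.0, 0.5, 0.25) * 1e-3), spl = 80)
  sm <- summarize_tf(tri)
  expect_equal(sm$best_frequency_hz, 6000)
  expect_equal(sm$lower_limit_hz, 4500)
  expect_equal(sm$upper_limit_hz, 7000)
  expect_equal(sm$range_hz, 2500)
  expect_false(sm$edge_clamped)

  # dB reference: 1 um/s is 0 dB, 1 mm/s is 60 dB
  mk <- function(vmax) build_transfer_function(
    data.frame(frequency_hz = c(1, 2, 3) * 1000,
               velocity_m_s = c(0.2, 1, 0.2) * vmax))
  expect_equal(summarize_tf(mk(1e-6))$velocity_db, 0)
  expect_equal(summarize_tf(mk(1e-3))$velocity_db, 60)

  # scale invariance of the frequency landmarks
  sc <- build_transfer_function(
    data.frame(frequency_hz = tri$frequency_hz,
               velocity_m_s = 7.3 * tri$velocity_m_s), spl = 80)
  sm_sc <- summarize_tf(sc)
  expect_equal(sm_sc$best_frequency_hz, sm$best_frequency_hz)
  expect_equal(sm_sc$lower_limit_hz, sm$lower_limit_hz)
  expect_equal(sm_sc$upper_limit_hz, sm$upper_limit_hz)
  expect_equal(sm_sc$max_velocity_m_s, 7.3 * sm$max_velocity_m_s)

  # curve never dropping below half-max clamps to the grid edge
  flat_ish <- build_transfer_function(
    data.frame(frequency_hz = c(1, 2, 3) * 1000,
               velocity_m_s = c(0.8, 1, 0.9) * 1e-3))
  sm_cl <- summarize_tf(flat_ish)
  expect_true(sm_cl$edge_clamped)
  expect_equal(sm_cl$lower_limit_hz, 1000)
  expect_equal(sm_cl$upper_limit_hz, 3000)

  # ties resolve to the lowest frequency
  tied <- build_transfer_function(
    data.frame(frequency_hz = c(1, 2, 3, 4) * 1000,
               velocity_m_s = c(0.1, 1, 1, 0.1) * 1e-3))
  expect_equal(summarize_tf(tied)$best_frequency_hz, 2000)

  expect_error(summarize_tf(build_transfer_function(
    data.frame(frequency_hz = c(1, 2, 3), velocity_m_s = c(0, 0, 0)))),
    "degenerate")
  expect_error(summarize_tf(build_transfer_function(
    data.frame(frequency_hz = c(1, 2), velocity_m_s = c(1, 2)))),
    "at least 3")
})

test_that("call-response spectra use whole-stimulus RMS and 97.66 Hz bins", {
  m <- eardrum_model(6300, noise_sd = noise_sd_10pct(1.2e-3),
                     peak_velocity_at_80db = 1.2e-3)
  reps <- simulate_call_response(m, southern_call(), spl = 80, n_reps = 8,
                                 seed = 3)
  spec <- call_response_spectrum(reps)
  expect_equal(spec$resolution_hz, 200000 / 2048)
  # the resonator imprints its peak near its center frequency; the downward
  # sweep of the call pulls the product peak slightly below it
  peak_f <- spec$frequency[which.max(spec$power)]
  expect_lt(abs(peak_f - 6300), 3 * spec$resolution_hz)

  # silence replicates give a flat near-zero spectrum
  silence <- replicate_set(lapply(1:4, function(k)
    waveform(numeric(40000), 200000)),
    list(duration_ms = 100, silence_ms = 100))
  quiet <- call_response_spectrum(silence)
  expect_equal(max(quiet$magnitude), 0)
})
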