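test_that("envelope measurements recover the printed call timings", {
  e_c <- measure_envelope(central_call())
  expect_equal(e_c$duration_ms, 71, tolerance = 2)
  expect_equal(e_c$time_to_max_ms, 26, tolerance = 2)

  e_s <- measure_envelope(southern_call())
  expect_equal(e_s$duration_ms, 42, tolerance = 2)
  expect_equal(e_s$time_to_max_ms, 19, tolerance = 2)

  # rectangular-envelope tone measures its full nominal duration
  tone <- waveform(sin(2 * pi * 2000 * seq_len(4410) / 44100), 44100)
  expect_equal(measure_envelope(tone)$duration_ms, 100, tolerance = 1)

  expect_error(measure_envelope(waveform(numeric(100), 44100)), "all-zero")
})

test_that("Welch spectrum has the right peak, flatness and power normalization", {
  sr <- 44100
  sine <- waveform(sin(2 * pi * 1000 * seq_len(sr) / sr), sr)
  spec <- power_spectrum(sine, 1024)
  expect_lt(abs(spec$frequency[which.max(spec$power)] - 1000),
            spec$resolution_hz)
  expect_equal(spec$resolution_hz, sr / 1024)

  noise <- waveform(with(list(), {set.seed(42); stats::rnorm(sr / 2)}), sr)
  nspec <- power_spectrum(noise, 1024)
  expect_gt(spectral_flatness(nspec), 0.9)
  # Parseval: total bin power matches the mean square of the signal
  expect_equal(sum(nspec$power), mean(noise$samples^2), tolerance = 0.01)

  expect_error(power_spectrum(sine, 1000), "power of two")
  expect_error(power_spectrum(waveform(numeric(100) + 1, sr), 1024), "shorter")
})

test_that("fundamental and dominant frequencies match the printed call values", {
  fd_c <- fundamental_and_dominant(central_call())
  expect_equal(fd_c$dominant_hz, 2700, tolerance = 44100 / 1024 / 2700)
  expect_equal(fd_c$fundamental_hz, 2700, tolerance = 0.03)

  fd_s <- fundamental_and_dominant(southern_call())
  expect_equal(fd_s$dominant_hz, 6300, tolerance = 44100 / 1024 / 6300)

  # strong tone + weaker octave: both measures sit at the lower tone
  t <- seq_len(8820) / 44100
  w <- waveform(sin(2 * pi * 1000 * t) + 0.4 * sin(2 * pi * 2000 * t), 44100)
  fd <- fundamental_and_dominant(w)
  expect_equal(fd$dominant_hz, 1000, tolerance = 0.05)
  expect_equal(fd$fundamental_hz, 1000, tolerance = 0.05)

  expect_error(fundamental_and_dominant(
    synthesize_noisy_call(47, 2000, 8000, 19, seed = 1)), "noise floor|harmonic")
})

test_that("harmonic counting reproduces the printed six and three", {
  expect_identical(count_harmonics(central_call(), 2700), 6L)
  expect_identical(count_harmonics(southern_call(), 6300), 3L)

  tone <- waveform(sin(2 * pi * 3000 * seq_len(4410) / 44100), 44100)
  expect_identical(count_harmonics(tone, 3000), 1L)

  expect_error(count_harmonics(tone, -1), "positive")
})

test_that("ultrasound flag keys on 20-22 kHz energy within 30 dB of the peak", {
  # low-frequency tone: nothing near 20 kHz
  low <- waveform(sin(2 * pi * 5000 * seq_len(44100) / 44100), 44100)
  expect_false(ultrasound_flag(low))

  # harmonic stack whose 7th harmonic at 21 kHz is 24 dB below the dominant
  stack <- synthesize_harmonic_call(
    call_params(7, 80, 25, 3000, 3000, harmonic_rolloff_db = 4))
  expect_true(ultrasound_flag(stack))

  # with a steep roll-off the 21 kHz component drops below the 30 dB window
  faint <- synthesize_harmonic_call(
    call_params(7, 80, 25, 3000, 3000, harmonic_rolloff_db = 7))
  expect_false(ultrasound_flag(faint))

  pure_us <- waveform(sin(2 * pi * 21000 * seq_len(44100) / 44100), 44100)
  expect_true(ultrasound_flag(pure_us))

  expect_error(ultrasound_flag(waveform(sin(1:100), 8000)), "20-22 kHz")
})

test_that("harmonic and noisy calls are classified correctly across seeds", {
  # harmonic calls with randomized in-range parameters: all classified harmonic
  set.seed(101)
  for (i in 1:25) {
    w <- synthesize_harmonic_call(random_call_params())
    expect_identical(classify_call_type(w), "harmonic")
  }
  expect_identical(classify_call_type(central_call()), "harmonic")
  expect_identical(classify_call_type(southern_call()), "harmonic")

  tone <- waveform(sin(2 * pi * 4000 * seq_len(8820) / 44100), 44100)
  expect_identical(classify_call_type(tone), "harmonic")

  # noisy calls: at least 95% classified noisy over 100 seeds
  verdicts <- vapply(1:100, function(s) {
    classify_call_type(synthesize_noisy_call(47, 2000, 8000, 19, seed = s))
  }, character(1))
  expect_gte(mean(verdicts == "noisy"), 0.95)

  expect_error(classify_call_type(waveform(numeric(100), 44100)), "silent")
})

test_that("FM patterns are classified from the f0 contour", {
  expect_identical(classify_fm_pattern(f0_track(central_call())), "downward")

  flat <- synthesize_harmonic_call(call_params(3, 60, 20, 4000, 4000))
  expect_identical(classify_fm_pattern(f0_track(flat)), "invariant")

  bell_track <- structure(list(times_ms = seq(0, 50, length.out = 21),
                               f0_hz = 3000 + 800 * sin(pi * seq(0, 1,
                                                                 length.out = 21)),
                               voiced = rep(TRUE, 21)),
                          class = "f0_track")
  expect_identical(classify_fm_pattern(bell_track), "bell")

  u_track <- bell_track
  u_track$f0_hz <- 3000 - 800 * sin(pi * seq(0, 1, length.out = 21))
  expect_identical(classify_fm_pattern(u_track), "u_shaped")

  up <- synthesize_harmonic_call(call_params(3, 60, 20, 3000, 3600))
  expect_identical(classify_fm_pattern(f0_track(up)), "upward")

  short <- structure(list(times_ms = 1:3, f0_hz = c(1, 2, 3) * 1000,
                          voiced = rep(TRUE, 3)), class = "f0_track")
  expect_error(classify_fm_pattern(short), "voiced frames")
})

test_that("FM classification is amplitude-invariant and flips under reversal", {
  w <- central_call()
  scaled <- waveform(0.25 * w$samples, w$sample_rate)
  expect_identical(classify_fm_pattern(f0_track(scaled)), "downward")

  reversed <- waveform(rev(w$samples), w$sample_rate)
  expect_identical(classify_fm_pattern(f0_track(reversed)), "upward")
})

test_that("measured features round-trip generator ground truth on random calls", {
  set.seed(202)
  n_runs <- 200
  ok <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    p <- random_call_params()
    w <- synthesize_harmonic_call(p)
    e <- measure_envelope(w)
    fd <- fundamental_and_dominant(w)
    nh <- count_harmonics(w, fd$fundamental_hz)
    ok[i] <- abs(e$duration_ms - p$duration_ms) <= 2 &&
      abs(e$time_to_max_ms - p$time_to_max_ms) <= 2 &&
      abs(fd$dominant_hz - p$f0_start_hz) <= 44100 / 1024 &&
      nh == p$n_harmonics
  }
  expect_gte(mean(ok), 0.95)
})

test_that("the full feature extractor assembles a coherent record", {
  feats <- call_features(central_call())
  expect_identical(feats$call_type, "harmonic")
  expect_identical(feats$n_harmonics, 6L)
  expect_identical(feats$fm_pattern, "downward")
  expect_false(feats$has_ultrasound)
  expect_gte(feats$dominant_hz, feats$fundamental_hz - 1e-9)

  noisy <- call_features(synthesize_noisy_call(47, 2000, 8000, 19, seed = 4))
  expect_identical(noisy$call_type, "noisy")
  expect_identical(noisy$n_harmonics, 0L)
  expect_true(is.na(noisy$fundamental_hz))
})
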