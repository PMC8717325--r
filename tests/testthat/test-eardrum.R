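test_that("noise-free simulation recovers the calibrated peak velocity", {
  stim <- make_tone_schedule(80)
  stim <- stim[stim$frequency_hz == 6200, ]
  m <- eardrum_model(6200, noise_sd = 0)
  reps <- simulate_tone_replicates(m, stim, n_reps = 4, seed = 1)
  v <- velocity_at_frequency(filter_and_average(reps), 6200)
  expect_equal(v, 1.4e-3, tolerance = 0.02)

  # above the high-frequency cutoff the response is at the noise floor
  hf <- make_tone_schedule(80)
  hf <- hf[hf$frequency_hz == 20000, ]
  reps_hf <- simulate_tone_replicates(m, hf, n_reps = 4, seed = 1)
  v_hf <- velocity_at_frequency(filter_and_average(reps_hf), 20000)
  expect_lt(v_hf, 0.01 * 1.4e-3)
})

test_that("simulation is reproducible and velocity is linear in dB drive", {
  stim <- make_tone_schedule(70)
  stim <- stim[stim$frequency_hz == 5000, ]
  m <- eardrum_model(5000, noise_sd = 0.05)
  a <- simulate_tone_replicates(m, stim, n_reps = 5, seed = 42)
  b <- simulate_tone_replicates(m, stim, n_reps = 5, seed = 42)
  for (k in 1:5) expect_identical(a$traces[[k]]$samples, b$traces[[k]]$samples)

  # velocity vs SPL has unit slope on the dB scale
  m0 <- eardrum_model(5000, noise_sd = 0)
  vels <- vapply(c(55, 60, 70, 80), function(spl) {
    s <- stim
    s$level_db_spl <- spl
    velocity_at_frequency(
      filter_and_average(simulate_tone_replicates(m0, s, 4, 1)), 5000)
  }, numeric(1))
  fit <- stats::lm(20 * log10(vels) ~ c(55, 60, 70, 80))
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 1e-6)
})

test_that("call responses behave as a linear filter with the right peak", {
  # flat unit-gain model passes the (rate-converted) call through unchanged
  flat <- eardrum_model(NA, noise_sd = 0)
  call <- southern_call()
  rs <- simulate_call_response(flat, call, spl = 94, n_reps = 1, seed = 1)
  n_call <- round(length(call$samples) * 200000 / call$sample_rate)
  passed <- rs$traces[[1]]$samples[seq_len(n_call)] / drive_scale(flat)
  resampled <- stats::approx(seq_along(call$samples), call$samples,
                             n = n_call)$y
  resampled <- resampled / max(abs(resampled))
  expect_lt(max(abs(passed - resampled)), 1e-9)

  # doubling the drive doubles the response RMS
  m <- eardrum_model(6300, noise_sd = 0)
  r1 <- simulate_call_response(m, call, spl = 74, n_reps = 1, seed = 1)
  r2 <- simulate_call_response(m, call, spl = 74 + 20 * log10(2),
                               n_reps = 1, seed = 1)
  expect_equal(rms(r2$traces[[1]]) / rms(r1$traces[[1]]), 2,
               tolerance = 1e-6)

  # a resonator driven by an unswept call at its center frequency leaves
  # the response spectrum peaked at that frequency
  mres <- eardrum_model(6300, noise_sd = 0)
  steady <- synthesize_harmonic_call(call_params(3, 42, 19, 6300, 6300))
  spec <- call_response_spectrum(
    simulate_call_response(mres, steady, 80, n_reps = 4, seed = 2))
  expect_lt(abs(spec$frequency[which.max(spec$power)] - 6300),
            2 * spec$resolution_hz)
})

test_that("population experiments produce the full factorial manifest", {
  spec <- population_spec(2, 5780, seed = 9)
  sched <- make_tone_schedule(c(60, 80))
  sched <- sched[sched$frequency_hz %in% c(1000, 5000, 9000), ]
  sim <- simulate_population_experiment(spec, sched, spls = c(60, 80),
                                        n_reps = 5)
  # 2 individuals x (6 tone stimuli + 2 calls x 2 SPLs) x 5 replicates
  expect_identical(nrow(sim$manifest), 2L * (6L + 4L) * 5L)
  expect_identical(length(sim$models), 2L)
  expect_identical(length(sim$replicate_sets), 2L)
  expect_identical(length(sim$replicate_sets[[1]]), 10L)

  # the full design, manifest only: 13 x (78 x 4 + 2 x 4) x 20 rows
  big <- simulate_population_experiment(population_spec(13, 5780, seed = 1),
                                        manifest_only = TRUE)
  expect_identical(nrow(big$manifest), 13L * (78L * 4L + 8L) * 20L)
})

test_that("cohort draws are seeded and bounded", {
  spec <- population_spec(50, 7170, sd_center_hz = 600, seed = 4)
  c1 <- draw_cohort(spec)
  c2 <- draw_cohort(spec)
  expect_identical(vapply(c1, `[[`, numeric(1), "center_frequency_hz"),
                   vapply(c2, `[[`, numeric(1), "center_frequency_hz"))
  fcs <- vapply(c1, `[[`, numeric(1), "center_frequency_hz")
  expect_equal(mean(fcs), 7170, tolerance = 0.05)
  expect_true(all(fcs < 12500))
})

test_that("end-to-end recovery of simulated eardrum parameters at 80 dB", {
  # moderate-size check of the recovery machinery (the full 200-run sweep
  # lives in the acceptance suite): center frequency to within one grid
  # step, peak velocity to within 5%, at 10% trace noise
  sched <- make_tone_schedule(80)
  sched <- sched[sched$frequency_hz >= 2000 & sched$frequency_hz <= 10000, ]
  set.seed(31)
  for (fc_true in c(3400, 6200, 9500)) {
    pv <- 1.3e-3
    m <- eardrum_model(fc_true, peak_velocity_at_80db = pv,
                       noise_sd = noise_sd_10pct(pv))
    vels <- vapply(seq_len(nrow(sched)), function(s) {
      reps <- simulate_tone_replicates(m, sched[s, ], n_reps = 20,
                                       seed = split_seed(31, j = s))
      velocity_at_frequency(filter_and_average(reps),
                            sched$frequency_hz[s])
    }, numeric(1))
    tf <- build_transfer_function(
      data.frame(frequency_hz = sched$frequency_hz, velocity_m_s = vels))
    sm <- summarize_tf(tf)
    grid_step <- if (fc_true <= 9000) 200 else 500
    expect_lte(abs(sm$best_frequency_hz - fc_true), grid_step)
    expect_equal(sm$max_velocity_m_s, pv, tolerance = 0.05)
  }
})
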