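#' Resonant eardrum model
#'
#' Phenomenological ground truth for simulated laser-vibrometry experiments:
#' a second-order resonator (single velocity peak at `center_frequency_hz`
#' with bandwidth set by `quality_factor`) combined with a steep
#' high-frequency roll-off above `hf_cutoff_hz`, reproducing the absence of
#' tympanic response above 12-14 kHz. The response is linear in the stimulus
#' amplitude and calibrated so that a tone at the center frequency at 80 dB
#' SPL produces `peak_velocity_at_80db`.
#'
#' @param center_frequency_hz Resonance (best) frequency, Hz. `NA` gives a
#'   flat unit-gain model (useful as an identity reference).
#' @param quality_factor Resonance quality factor (default 4; for a
#'   second-order resonator the half-velocity bandwidth is
#'   `sqrt(3) * fc / Q`, so Q = 4 near 6 kHz yields the roughly 2.5-kHz
#'   half-maximum sensitivity ranges seen in tympanic recordings).
#' @param peak_velocity_at_80db Velocity at the center frequency for an
#'   80 dB SPL tone, m/s (default 1.4e-3).
#' @param noise_sd Additive Gaussian noise on each trace, in trace units
#'   (default 0).
#' @param hf_cutoff_hz Frequency above which the response is nulled by a
#'   4th-order low-pass (default 13000).
#' @return A list of class `eardrum_model`.
#' @export
eardrum_model <- function(center_frequency_hz,
                          quality_factor = 4,
                          peak_velocity_at_80db = 1.4e-3,
                          noise_sd = 0,
                          hf_cutoff_hz = 13000) {
  if (!is.na(center_frequency_hz) && center_frequency_hz >= hf_cutoff_hz) {
    stop("center frequency must lie below the high-frequency cutoff",
         call. = FALSE)
  }
  if (quality_factor <= 0) stop("quality_factor must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(center_frequency_hz = center_frequency_hz,
                 quality_factor = quality_factor,
                 peak_velocity_at_80db = peak_velocity_at_80db,
                 noise_sd = noise_sd,
                 hf_cutoff_hz = hf_cutoff_hz),
            class = "eardrum_model")
}

#' @export
print.eardrum_model <- function(x, ...) {
  if (is.na(x$center_frequency_hz)) {
    cat("<eardrum_model: flat unit-gain reference>\n")
  } else {
    cat(sprintf(paste0("<eardrum_model: fc %.2f kHz, Q %.2g, ",
                       "%.3g mm/s at 80 dB, noise sd %.3g, LP %.1f kHz>\n"),
                x$center_frequency_hz / 1000, x$quality_factor,
                x$peak_velocity_at_80db * 1000, x$noise_sd,
                x$hf_cutoff_hz / 1000))
  }
  invisible(x)
}

# Digital trace units per m/s implied by the acquisition chain defaults
# (5 mm/s per volt sensitivity, 20 dB amplifier gain, 1 V per unit).
trace_units_per_m_s <- function(sensitivity_m_s = 0.005, gain_db = 20) {
  10^(gain_db / 20) / sensitivity_m_s
}

# Normalized resonator magnitude response on a frequency grid: second-order
# band-pass magnitude times a 4th-order low-pass, scaled to 1 at fc.
resonator_gain <- function(model, freq) {
  if (is.na(model$center_frequency_hz)) return(rep(1, length(freq)))
  fc <- model$center_frequency_hz
  q <- model$quality_factor
  bp <- function(f) {
    (f * fc / q) / sqrt((fc^2 - f^2)^2 + (f * fc / q)^2)
  }
  lp <- function(f) 1 / sqrt(1 + (f / model$hf_cutoff_hz)^16)
  bp(freq) * lp(freq) / (bp(fc) * lp(fc))
}

# Zero-phase application of the resonator magnitude response via the FFT.
apply_resonator <- function(model, x, sample_rate) {
  n <- length(x)
  freq <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) *
    sample_rate / n
  H <- resonator_gain(model, abs(freq))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE) / n)
}

# One seeded draw of the whole noise matrix per replicate set: replicate k is
# base + column k. A single substream per (individual, stimulus) keeps runs
# reproducible while avoiding per-replicate RNG re-seeding.
add_replicate_noise <- function(base, noise_sd, n_reps, seed, sample_rate) {
  n <- length(base)
  if (noise_sd > 0) {
    noise <- with_seed(seed,
                       matrix(stats::rnorm(n * n_reps, sd = noise_sd),
                              nrow = n))
    lapply(seq_len(n_reps),
           function(k) waveform(base + noise[, k], sample_rate))
  } else {
    lapply(seq_len(n_reps), function(k) waveform(base, sample_rate))
  }
}

# Overall scale from digital drive amplitude to trace units such that a tone
# at fc at 80 dB SPL comes out at peak_velocity_at_80db.
drive_scale <- function(model, reference_db = 94) {
  amp80 <- 10^((80 - reference_db) / 20)
  model$peak_velocity_at_80db * trace_units_per_m_s() / amp80
}

#' Simulate vibrometer replicates for a tone stimulus
#'
#' Each trace is the tone filtered by the resonator response (zero above the
#' high-frequency cutoff), scaled so the velocity is linear in the stimulus
#' sound pressure, plus independent Gaussian noise. Traces are in digital
#' trace units, matching what [velocity_at_frequency()] expects.
#'
#' @param model An [eardrum_model].
#' @param stim A tone stimulus (row of [make_tone_schedule()]).
#' @param n_reps Number of replicates (default 20).
#' @param seed Integer seed for the replicate-noise draw; the same seed
#'   reproduces the traces bit-identically. Callers simulating many stimuli
#'   derive one substream per (individual, stimulus) with [split_seed()].
#' @param sample_rate Acquisition rate, Hz (default 200000).
#' @return A [replicate_set].
#' @export
simulate_tone_replicates <- function(model, stim, n_reps = 20, seed = 1L,
                                     sample_rate = 200000) {
  stopifnot(inherits(model, "eardrum_model"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  stim <- as.list(stim)
  tone <- synthesize_tone(stim, sample_rate = sample_rate)
  base <- apply_resonator(model, tone$samples, sample_rate) * drive_scale(model)
  replicate_set(add_replicate_noise(base, model$noise_sd, n_reps, seed,
                                    sample_rate),
                stim)
}

#' Simulate vibrometer replicates for a call stimulus
#'
#' The call is resampled to the acquisition rate, scaled to the requested
#' sound pressure level, filtered through the resonator and followed by an
#' equal-duration silence interval; independent Gaussian noise is added per
#' replicate.
#'
#' @param model An [eardrum_model].
#' @param call A [waveform] holding the synthetic call (any sample rate).
#' @param spl Playback level, dB SPL.
#' @param n_reps Number of replicates (default 20).
#' @param seed Integer base seed.
#' @param sample_rate Acquisition rate, Hz (default 200000).
#' @param reference_db SPL corresponding to unit digital amplitude.
#' @param call_id Label stored with the stimulus (default "call").
#' @return A [replicate_set]; the stimulus `duration_ms` equals the call
#'   duration and `silence_ms` matches it.
#' @export
simulate_call_response <- function(model, call, spl, n_reps = 20, seed = 1L,
                                   sample_rate = 200000, reference_db = 94,
                                   call_id = "call") {
  stopifnot(inherits(model, "eardrum_model"))
  assert_waveform(call)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  x <- call$samples
  if (call$sample_rate != sample_rate) {
    n_out <- round(length(x) * sample_rate / call$sample_rate)
    x <- stats::approx(seq_along(x), x, n = n_out)$y
  }
  x <- x / max(abs(x)) * 10^((spl - reference_db) / 20)
  x <- c(x, numeric(length(x)))          # silence interval of equal duration
  base <- apply_resonator(model, x, sample_rate) * drive_scale(model)
  traces <- add_replicate_noise(base, model$noise_sd, n_reps, seed,
                                sample_rate)
  duration_ms <- length(x) / 2 / sample_rate * 1000
  replicate_set(traces, list(call_id = call_id, duration_ms = duration_ms,
                             silence_ms = duration_ms, level_db_spl = spl))
}

#' Population specification for simulated cohorts
#'
#' Describes a cohort of simulated eardrums: individual center frequencies
#' and peak velocities are drawn from normal distributions around the
#' population means.
#'
#' @param n_individuals Cohort size.
#' @param mean_center_hz,sd_center_hz Center-frequency distribution, Hz.
#' @param mean_peak_velocity,sd_peak_velocity Peak velocity at 80 dB, m/s.
#' @param noise_sd Trace noise sd passed to each [eardrum_model].
#' @param seed Integer seed for the cohort draw.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_individuals,
                            mean_center_hz, sd_center_hz = 600,
                            mean_peak_velocity = 1.4e-3,
                            sd_peak_velocity = 2e-4,
                            noise_sd = 0, seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals),
                 mean_center_hz = mean_center_hz,
                 sd_center_hz = sd_center_hz,
                 mean_peak_velocity = mean_peak_velocity,
                 sd_peak_velocity = sd_peak_velocity,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Draw the individual eardrum models of a cohort
#'
#' @param spec A [population_spec].
#' @return A list of [eardrum_model]s, one per individual.
#' @export
draw_cohort <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, {
    fc <- stats::rnorm(spec$n_individuals, spec$mean_center_hz,
                       spec$sd_center_hz)
    pv <- stats::rnorm(spec$n_individuals, spec$mean_peak_velocity,
                       spec$sd_peak_velocity)
  })
  fc <- pmin(pmax(fc, 500), 12500)
  pv <- pmax(pv, 1e-5)
  lapply(seq_len(spec$n_individuals), function(i) {
    eardrum_model(center_frequency_hz = fc[i],
                  peak_velocity_at_80db = pv[i],
                  noise_sd = spec$noise_sd)
  })
}

#' Simulate a full population experiment
#'
#' Draws a cohort from the specification and simulates the complete stimulus
#' protocol for each individual: every scheduled tone frequency at every
#' sound level, plus both synthetic population calls, each with `n_reps`
#' replicates. The returned manifest has one row per recorded trace,
#' mirroring the on-disk layout the vibrometry stage consumes; with
#' `out_dir` set, traces are also written as WAV files next to a
#' `manifest.csv`. With `manifest_only = TRUE` no traces are generated
#' (useful to inspect the experimental design).
#'
#' @param spec A [population_spec].
#' @param schedule A tone schedule (default [make_tone_schedule()]).
#' @param spls Sound levels for the call stimuli (default unique schedule
#'   levels).
#' @param calls Named list of call [waveform]s (default: the two synthetic
#'   population calls).
#' @param n_reps Replicates per stimulus (default 20).
#' @param out_dir Optional directory for WAV traces + manifest.csv.
#' @param manifest_only Skip trace synthesis entirely (default FALSE).
#' @param population Population label recorded in the manifest.
#' @return A list with `models` (the cohort), `manifest` (data frame with
#'   columns `file`, `individual`, `population`, `stimulus_type`,
#'   `frequency_hz`, `call_id`, `spl_db`, `replicate`) and, unless
#'   `manifest_only`, `replicate_sets` (nested list indexed by individual,
#'   then stimulus key).
#' @export
simulate_population_experiment <- function(spec,
                                           schedule = make_tone_schedule(),
                                           spls = NULL,
                                           calls = NULL,
                                           n_reps = 20,
                                           out_dir = NULL,
                                           manifest_only = FALSE,
                                           population = "central") {
  stopifnot(inherits(spec, "population_spec"))
  if (is.null(spls)) spls <- unique(schedule$level_db_spl)
  if (is.null(calls)) {
    calls <- list(central = synthesize_harmonic_call(population_call_params("central")),
                  southern = synthesize_harmonic_call(population_call_params("southern")))
  }
  models <- draw_cohort(spec)

  rows <- list()
  sets <- if (!manifest_only) list() else NULL
  for (i in seq_len(spec$n_individuals)) {
    id <- sprintf("%s_%02d", population, i)
    if (!manifest_only) sets[[id]] <- list()
    stim_idx <- 0L
    for (s in seq_len(nrow(schedule))) {
      stim_idx <- stim_idx + 1L
      stim <- schedule[s, ]
      key <- sprintf("tone_%g_%g", stim$frequency_hz, stim$level_db_spl)
      rows[[length(rows) + 1]] <- data.frame(
        file = sprintf("%s_%s_rep%02d.wav", id, key, seq_len(n_reps)),
        individual = id, population = population, stimulus_type = "tone",
        frequency_hz = stim$frequency_hz, call_id = NA_character_,
        spl_db = stim$level_db_spl, replicate = seq_len(n_reps)
      )
      if (!manifest_only) {
        sets[[id]][[key]] <- simulate_tone_replicates(
          models[[i]], stim, n_reps = n_reps,
          seed = split_seed(spec$seed, i = i, j = stim_idx))
      }
    }
    for (call_id in names(calls)) {
      for (spl in spls) {
        stim_idx <- stim_idx + 1L
        key <- sprintf("call_%s_%g", call_id, spl)
        rows[[length(rows) + 1]] <- data.frame(
          file = sprintf("%s_%s_rep%02d.wav", id, key, seq_len(n_reps)),
          individual = id, population = population, stimulus_type = "call",
          frequency_hz = NA_real_, call_id = call_id, spl_db = spl,
          replicate = seq_len(n_reps)
        )
        if (!manifest_only) {
          sets[[id]][[key]] <- simulate_call_response(
            models[[i]], calls[[call_id]], spl = spl, n_reps = n_reps,
            seed = split_seed(spec$seed, i = i, j = stim_idx),
            call_id = call_id)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL

  if (!is.null(out_dir) && !manifest_only) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(sets)) {
      for (key in names(sets[[id]])) {
        rs <- sets[[id]][[key]]
        for (k in seq_len(rs$n_replicates)) {
          tr <- rs$traces[[k]]
          peak <- max(abs(tr$samples), 1e-12)
          scaled <- waveform(tr$samples / max(peak, 1), tr$sample_rate)
          write_wav(scaled, file.path(out_dir,
                                      sprintf("%s_%s_rep%02d.wav", id, key, k)))
        }
      }
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(models = models, manifest = manifest, replicate_sets = sets)
}
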