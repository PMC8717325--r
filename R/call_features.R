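#' Welch-averaged magnitude spectrum
#'
#' Magnitude spectrum averaged over Hamming-windowed frames with the stated
#' overlap (spectrogram-style analysis: FFT length 1024 with 87.5% overlap by
#' default). Power is normalized so that the summed bin powers estimate the
#' mean square of the signal.
#'
#' @param wave A [waveform] at least `n_fft` samples long.
#' @param n_fft Transform length; must be a power of two.
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.875).
#' @return An object of class `power_spectrum` with fields `frequency`
#'   (Hz, one-sided grid), `magnitude`, `power`, `resolution_hz`, `n_frames`.
#' @export
power_spectrum <- function(wave, n_fft = 1024, overlap = 0.875) {
  assert_waveform(wave)
  if (n_fft < 2 || bitwAnd(n_fft, n_fft - 1L) != 0) {
    stop("n_fft must be a power of two", call. = FALSE)
  }
  x <- wave$samples
  if (length(x) < n_fft) {
    stop("waveform shorter than the FFT length", call. = FALSE)
  }
  hop <- max(1L, round(n_fft * (1 - overlap)))
  starts <- seq(1L, length(x) - n_fft + 1L, by = hop)
  w <- hamming_window(n_fft)
  norm <- n_fft * sum(w^2)
  n_bins <- n_fft / 2 + 1
  acc <- numeric(n_bins)
  for (s in starts) {
    X <- stats::fft(x[s:(s + n_fft - 1)] * w)
    p <- Mod(X[seq_len(n_bins)])^2
    p[2:(n_bins - 1)] <- 2 * p[2:(n_bins - 1)]   # fold negative frequencies
    acc <- acc + p / norm
  }
  p_mean <- acc / length(starts)
  new_power_spectrum(
    frequency = (seq_len(n_bins) - 1) * wave$sample_rate / n_fft,
    power = p_mean,
    resolution_hz = wave$sample_rate / n_fft,
    n_frames = length(starts)
  )
}

new_power_spectrum <- function(frequency, power, resolution_hz, n_frames = 1L) {
  structure(list(frequency = frequency,
                 magnitude = sqrt(power),
                 power = power,
                 resolution_hz = resolution_hz,
                 n_frames = n_frames),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum: %d bins, %g-%g Hz @ %.4g Hz resolution>\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              x$resolution_hz))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, db = TRUE, ...) {
  y <- if (db) 20 * log10(pmax(x$magnitude, 1e-12) / max(x$magnitude)) else x$magnitude
  graphics::plot(x$frequency / 1000, y, type = "l", xlab = "Frequency (kHz)",
                 ylab = if (db) "Level (dB re max)" else "Magnitude", ...)
  invisible(x)
}

#' Spectral flatness of a spectrum
#'
#' Geometric over arithmetic mean of bin powers; 1 for white noise, near 0
#' for line spectra.
#'
#' @param spec A `power_spectrum`.
#' @return Flatness in `[0, 1]`.
#' @export
spectral_flatness <- function(spec) {
  p <- spec$power[spec$power > 0]
  exp(mean(log(p))) / mean(p)
}

#' Measure call duration and time to maximum amplitude
#'
#' Onset and offset are the first and last crossings of the smoothed amplitude
#' envelope through a relative threshold (default -20 dB below the envelope
#' peak, an operational stand-in for reading oscillograms by eye). The time to
#' maximum amplitude is measured from onset to the envelope maximum.
#'
#' @param wave A [waveform]; must not be all-zero.
#' @param threshold_db Onset/offset threshold relative to the envelope peak,
#'   dB (default -20).
#' @param smooth_ms Envelope smoothing window, ms (default 2).
#' @return A list with `duration_ms`, `time_to_max_ms`, `onset_ms`,
#'   `offset_ms`.
#' @export
measure_envelope <- function(wave, threshold_db = -20, smooth_ms = 2) {
  assert_waveform(wave)
  if (all(wave$samples == 0)) stop("cannot measure an all-zero call", call. = FALSE)
  env <- amplitude_envelope(wave, smooth_ms)
  thr <- max(env) * 10^(threshold_db / 20)
  above <- which(env >= thr)
  onset <- above[1]
  offset <- above[length(above)]
  i_max <- which.max(env)
  to_ms <- function(i) (i - 1) / wave$sample_rate * 1000
  list(duration_ms = to_ms(offset) - to_ms(onset),
       time_to_max_ms = to_ms(i_max) - to_ms(onset),
       onset_ms = to_ms(onset),
       offset_ms = to_ms(offset))
}

# Zero-padded Hamming-windowed magnitude spectrum of a short onset segment.
# Frequencies and the instantaneous fundamental are nearly stationary over a
# few milliseconds, which is what makes the nominal (onset) fundamental of a
# swept call measurable.
onset_spectrum <- function(wave, onset_ms = 3, pad_to = 8192) {
  env <- measure_envelope(wave)
  i0 <- round(env$onset_ms / 1000 * wave$sample_rate) + 1
  len <- max(64L, round(onset_ms / 1000 * wave$sample_rate))
  i1 <- min(length(wave$samples), i0 + len - 1)
  seg <- wave$samples[i0:i1]
  w <- hamming_window(length(seg))
  n <- max(pad_to, next_pow2(length(seg)))
  X <- stats::fft(c(seg * w, numeric(n - length(seg))))
  n_bins <- n / 2 + 1
  # resolution_hz here is the padded grid spacing; the physical resolution is
  # set by the segment length (main-lobe width), which callers account for
  new_power_spectrum(frequency = (seq_len(n_bins) - 1) * wave$sample_rate / n,
                     power = Mod(X[seq_len(n_bins)])^2,
                     resolution_hz = wave$sample_rate / n)
}

# Hamming main-lobe half-width for a segment of n_seg samples
lobe_halfwidth_hz <- function(sample_rate, n_seg) 2 * sample_rate / n_seg

#' Fundamental and dominant frequency of a harmonic call
#'
#' The dominant frequency is the location of the global maximum of the
#' magnitude spectrum of a short segment at the call onset (the segment free
#' of nonlinear phenomena, at the beginning of the signal). The fundamental is
#' the best harmonic-comb root explaining the set of prominent spectral peaks
#' (an approximate greatest common divisor), which is robust when the
#' fundamental is weaker than a higher harmonic.
#'
#' @param wave A [waveform] carrying a harmonic call.
#' @param onset_ms Length of the onset analysis segment, ms (default 3).
#' @param min_f0 Lowest admissible fundamental, Hz (default 300).
#' @return A list with `fundamental_hz` and `dominant_hz`.
#' @export
fundamental_and_dominant <- function(wave, onset_ms = 3, min_f0 = 300) {
  spec <- onset_spectrum(wave, onset_ms)
  keep <- spec$frequency >= min_f0
  f <- spec$frequency[keep]
  m <- spec$magnitude[keep]
  floor_db <- 20 * log10(max(m) / stats::median(m[m > 0]))
  if (!is.finite(floor_db) || floor_db < 10 ||
      harmonicity_score(wave) <= 0.5) {
    stop("no clear harmonic structure above the noise floor: noisy call",
         call. = FALSE)
  }
  dominant <- f[which.max(m)]

  n_seg <- max(64L, round(onset_ms / 1000 * wave$sample_rate))
  lobe <- lobe_halfwidth_hz(wave$sample_rate, n_seg)
  peaks <- find_spectral_peaks(f, m, min_prominence_db = 10,
                               min_separation_hz = lobe)
  # candidate comb roots: each peak divided by small integers
  cands <- unique(unlist(lapply(peaks, function(p) p / 1:4)))
  cands <- cands[cands >= min_f0]
  best <- dominant
  best_explained <- -1
  for (cand in sort(cands, decreasing = TRUE)) {
    tol <- pmax(0.03 * peaks, lobe)
    k <- round(peaks / cand)
    ok <- k >= 1 & abs(peaks - k * cand) <= tol
    explained <- sum(ok)
    if (explained > best_explained && any(ok & abs(peaks - dominant) < lobe)) {
      best_explained <- explained
      best <- cand
    }
  }
  # snap the comb root to an exact integer divisor of the dominant peak, so
  # the dominant is a harmonic of the reported fundamental by construction
  fundamental <- dominant / max(1, round(dominant / best))
  list(fundamental_hz = fundamental, dominant_hz = dominant)
}

# Local maxima of a magnitude spectrum at least `min_prominence_db` above the
# spectral median and within `dynamic_range_db` of the spectral maximum
# (emulating the display dynamic range of a spectrogram), separated by at
# least `min_separation_hz`.
find_spectral_peaks <- function(f, m, min_prominence_db = 10,
                                min_separation_hz = 0,
                                dynamic_range_db = 35) {
  thr <- max(stats::median(m[m > 0]) * 10^(min_prominence_db / 20),
             max(m) * 10^(-dynamic_range_db / 20))
  n <- length(m)
  is_peak <- c(FALSE, m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n],
               FALSE) & m > thr
  pf <- f[is_peak]
  pm <- m[is_peak]
  ord <- order(pm, decreasing = TRUE)
  kept <- numeric(0)
  for (i in ord) {
    if (all(abs(pf[i] - kept) > min_separation_hz)) kept <- c(kept, pf[i])
  }
  sort(kept)
}

#' Count harmonics of a call
#'
#' Number of harmonic indices `k` whose comb position `k * fundamental_hz`
#' carries a spectral peak at least 10 dB above the spectral median, within a
#' tolerance of 3% of the comb line (never tighter than the analysis
#' resolution). Measured on the quasi-stationary onset segment, mirroring
#' harmonic counting on spectrograms at the beginning of the signal.
#'
#' @param wave A [waveform].
#' @param fundamental_hz The call fundamental, Hz.
#' @param onset_ms Onset segment length, ms (default 3).
#' @param margin_db Required prominence above the spectral median (default 10).
#' @param dynamic_range_db Floor below the spectral maximum beyond which a
#'   component no longer counts as recognizable (default 35, the typical
#'   display dynamic range of a spectrogram).
#' @return Integer harmonic count.
#' @export
count_harmonics <- function(wave, fundamental_hz, onset_ms = 3,
                            margin_db = 10, dynamic_range_db = 35) {
  if (!is.numeric(fundamental_hz) || fundamental_hz <= 0) {
    stop("fundamental_hz must be positive", call. = FALSE)
  }
  spec <- onset_spectrum(wave, onset_ms)
  med <- stats::median(spec$magnitude[spec$magnitude > 0])
  thr <- max(med * 10^(margin_db / 20),
             max(spec$magnitude) * 10^(-dynamic_range_db / 20))
  n_seg <- max(64L, round(onset_ms / 1000 * wave$sample_rate))
  lobe <- lobe_halfwidth_hz(wave$sample_rate, n_seg)
  nyq <- wave$sample_rate / 2
  count <- 0L
  k <- 1L
  repeat {
    target <- k * fundamental_hz
    tol <- max(0.03 * target, lobe)
    if (target + tol >= nyq || k > 40L) break
    in_win <- abs(spec$frequency - target) <= tol
    if (any(spec$magnitude[in_win] > thr)) count <- count + 1L
    k <- k + 1L
  }
  count
}

#' Flag ultrasonic components
#'
#' TRUE when the 20-22 kHz band carries power within `margin_db` (default 30)
#' of the dominant spectral peak. Calls whose energy decreases gradually into
#' this band are taken to extend into the ultrasonic range, which a 22-kHz
#' bandwidth recording cannot observe directly.
#'
#' @param wave A [waveform] sampled at 44.1 kHz or higher.
#' @param margin_db Maximum allowed drop below the dominant peak, dB.
#' @param band Band taken as evidence of ultrasound, Hz.
#' @return Logical flag.
#' @export
ultrasound_flag <- function(wave, margin_db = 30, band = c(20000, 22000)) {
  assert_waveform(wave)
  if (wave$sample_rate / 2 < band[2]) {
    stop("sample rate too low to assess the 20-22 kHz band", call. = FALSE)
  }
  n_fft <- min(1024L, next_pow2(length(wave$samples)) / 2)
  spec <- power_spectrum(wave, n_fft = n_fft)
  peak <- max(spec$power)
  in_band <- spec$frequency >= band[1] & spec$frequency <= band[2]
  band_peak <- max(spec$power[in_band])
  10 * log10(band_peak / peak) >= -margin_db
}

#' Frame-wise harmonicity score
#'
#' For each Hamming-windowed frame the most plausible comb root is selected
#' (frame peak divided by small integers) and the score is the fraction of
#' frame spectral energy lying within a tolerance of the comb lines (3% of
#' each line, never tighter than the frame resolution). Frames are combined
#' weighted by their energy. Harmonic calls score high even when the
#' fundamental sweeps; turbulent noise scores low.
#'
#' @param wave A [waveform].
#' @param frame Frame length in samples (default 512).
#' @param hop Hop between frames (default `frame / 2`).
#' @param min_f0 Lowest admissible comb root, Hz (default 1000).
#' @return Score in `[0, 1]`.
#' @export
harmonicity_score <- function(wave, frame = 512L, hop = frame %/% 2L,
                              min_f0 = 1000) {
  assert_waveform(wave)
  x <- wave$samples
  if (length(x) < frame) {
    x <- c(x, numeric(frame - length(x)))
  }
  sr <- wave$sample_rate
  w <- hamming_window(frame)
  n_bins <- frame / 2 + 1
  freqs <- (seq_len(n_bins) - 1) * sr / frame
  lobe <- 2 * sr / frame
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  peak_env <- max(abs(x))
  scores <- weights <- numeric(0)
  for (s in starts) {
    seg <- x[s:(s + frame - 1)]
    if (max(abs(seg)) < 0.05 * peak_env) next
    p <- Mod(stats::fft(seg * w)[seq_len(n_bins)])^2
    p[1] <- 0
    tot <- sum(p)
    if (tot <= 0) next
    fpk <- freqs[which.max(p)]
    cands <- fpk / 1:4
    cands <- cands[cands >= min_f0]
    if (length(cands) == 0) cands <- max(fpk, min_f0)
    best <- 0
    for (cand in cands) {
      k <- pmax(1, round(freqs / cand))
      line <- k * cand
      tol <- pmax(0.03 * line, lobe)
      best <- max(best, sum(p[abs(freqs - line) <= tol]) / tot)
    }
    scores <- c(scores, best)
    weights <- c(weights, tot)
  }
  if (length(scores) == 0) return(0)
  sum(scores * weights) / sum(weights)
}

#' Classify a call as harmonic or noisy
#'
#' Harmonic when the frame-wise [harmonicity_score()] exceeds `threshold`
#' (default 0.5): calls with a clear (possibly swept) harmonic structure pass,
#' turbulent non-harmonic calls do not.
#'
#' @param wave A non-silent [waveform].
#' @param threshold Harmonicity threshold (default 0.5).
#' @param ... Passed on to [harmonicity_score()].
#' @return `"harmonic"` or `"noisy"`.
#' @export
classify_call_type <- function(wave, threshold = 0.5, ...) {
  assert_waveform(wave)
  if (all(wave$samples == 0)) stop("cannot classify a silent call", call. = FALSE)
  if (harmonicity_score(wave, ...) > threshold) "harmonic" else "noisy"
}

#' Fundamental-frequency track
#'
#' Frame-wise fundamental estimated from the normalized autocorrelation peak
#' (with parabolic interpolation of the lag), the standard pitch-tracking
#' approach for harmonic signals. Frames with weak periodicity or low energy
#' are marked unvoiced.
#'
#' @param wave A [waveform].
#' @param frame_ms Frame length, ms (default 10).
#' @param hop_ms Hop between frames, ms (default 2.5).
#' @param f0_range Admissible fundamental range, Hz.
#' @param voicing_threshold Minimum normalized autocorrelation at the pitch
#'   lag for a frame to count as voiced (default 0.4).
#' @return An object of class `f0_track`: list with `times_ms`, `f0_hz`,
#'   `voiced`.
#' @export
f0_track <- function(wave, frame_ms = 10, hop_ms = 2.5,
                     f0_range = c(300, 10000), voicing_threshold = 0.4) {
  assert_waveform(wave)
  sr <- wave$sample_rate
  frame <- round(frame_ms / 1000 * sr)
  hop <- max(1L, round(hop_ms / 1000 * sr))
  x <- wave$samples
  lag_min <- max(2L, floor(sr / f0_range[2]))
  lag_max <- ceiling(sr / f0_range[1])
  if (lag_max >= frame) stop("frame too short for the requested f0 range",
                             call. = FALSE)
  starts <- seq(1L, max(1L, length(x) - frame + 1L), by = hop)
  peak_amp <- max(abs(x))
  times <- f0s <- numeric(length(starts))
  voiced <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    seg <- x[s:min(length(x), s + frame - 1)]
    if (length(seg) < frame) seg <- c(seg, numeric(frame - length(seg)))
    seg <- seg - mean(seg)
    times[i] <- (s - 1 + frame / 2) / sr * 1000
    if (max(abs(seg)) < 0.02 * peak_amp) next
    n2 <- 2 * frame
    ac <- Re(stats::fft(Mod(stats::fft(c(seg, numeric(frame))))^2,
                        inverse = TRUE))[seq_len(frame)] / n2
    ac <- ac / ac[1]
    lag_hi <- min(lag_max, frame - 2L)
    window <- ac[(lag_min + 1):(lag_hi + 1)]
    if (max(window) < voicing_threshold) next
    # prefer the shortest lag among near-maximal peaks (octave-error guard)
    nw <- length(window)
    loc_max <- c(window[1] > window[2],
                 window[2:(nw - 1)] >= window[1:(nw - 2)] &
                   window[2:(nw - 1)] >= window[3:nw],
                 window[nw] > window[nw - 1])
    cand <- which(loc_max & window >= 0.85 * max(window))
    j <- if (length(cand) > 0) cand[1] else which.max(window)
    lag <- lag_min + j - 1
    # parabolic interpolation of the autocorrelation peak
    if (lag > lag_min && lag < lag_hi) {
      y1 <- ac[lag]; y2 <- ac[lag + 1]; y3 <- ac[lag + 2]
      denom <- y1 - 2 * y2 + y3
      shift <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
      lag <- lag + shift
    }
    f0s[i] <- sr / lag
    voiced[i] <- TRUE
  }
  structure(list(times_ms = times, f0_hz = f0s, voiced = voiced),
            class = "f0_track")
}

#' Classify the frequency-modulation pattern of a call
#'
#' Categorizes the voiced fundamental contour as `downward`, `upward`,
#' `invariant` (total relative change below 5%), `bell` (interior maximum
#' exceeding the endpoint span) or `u_shaped` (interior minimum exceeding the
#' endpoint span). The decision is invariant to amplitude scaling and maps
#' downward to upward under time reversal.
#'
#' @param track An `f0_track` (or a [waveform], which is tracked first).
#' @param invariant_tol Relative f0 range below which the contour counts as
#'   invariant (default 0.05).
#' @return One of `"downward"`, `"upward"`, `"invariant"`, `"bell"`,
#'   `"u_shaped"`.
#' @export
classify_fm_pattern <- function(track, invariant_tol = 0.05) {
  if (is_waveform(track)) track <- f0_track(track)
  stopifnot(inherits(track, "f0_track"))
  f <- track$f0_hz[track$voiced]
  if (length(f) < 5) {
    stop("need at least 5 voiced frames to classify an FM pattern",
         call. = FALSE)
  }
  f <- moving_average(stats::runmed(f, 3), 3)   # robust to octave slips
  n <- length(f)
  # average a few frames at each end to stabilize the endpoints
  m <- max(1L, n %/% 10L)
  f_start <- mean(f[seq_len(m)])
  f_end <- mean(f[(n - m + 1):n])
  if ((max(f) - min(f)) / mean(f) < invariant_tol) return("invariant")
  net <- f_end - f_start
  rise <- max(f) - max(f_start, f_end)   # interior maximum above both ends
  dip <- min(f_start, f_end) - min(f)    # interior minimum below both ends
  i_max <- which.max(f)
  i_min <- which.min(f)
  interior <- function(i) i > m && i <= n - m
  if (interior(i_max) && rise > abs(net) && rise >= dip) return("bell")
  if (interior(i_min) && dip > abs(net) && dip > rise) return("u_shaped")
  if (net < 0) "downward" else "upward"
}

#' Extract the full spectro-temporal feature set of a call
#'
#' Runs the complete measurement chain: envelope timing, call-type
#' classification, fundamental/dominant frequencies and harmonic count (for
#' harmonic calls), ultrasound flag (when the bandwidth allows) and FM
#' pattern.
#'
#' @param wave A [waveform].
#' @return A list of class `call_features`.
#' @export
call_features <- function(wave) {
  assert_waveform(wave)
  env <- measure_envelope(wave)
  type <- classify_call_type(wave)
  has_us <- if (wave$sample_rate / 2 >= 22000) ultrasound_flag(wave) else NA
  if (type == "harmonic") {
    fd <- fundamental_and_dominant(wave)
    nh <- count_harmonics(wave, fd$fundamental_hz)
    fm <- tryCatch(classify_fm_pattern(f0_track(wave)),
                   error = function(e) NA_character_)
  } else {
    fd <- list(fundamental_hz = NA_real_, dominant_hz = NA_real_)
    nh <- 0L
    fm <- NA_character_
  }
  structure(list(duration_ms = env$duration_ms,
                 time_to_max_ms = env$time_to_max_ms,
                 fundamental_hz = fd$fundamental_hz,
                 dominant_hz = fd$dominant_hz,
                 n_harmonics = nh,
                 has_ultrasound = has_us,
                 call_type = type,
                 fm_pattern = fm),
            class = "call_features")
}

#' @export
print.call_features <- function(x, ...) {
  cat(sprintf(paste0("<call_features: %s call, %.1f ms (max at %.1f ms), ",
                     "f0 %.0f Hz, dominant %.0f Hz, %d harmonics, ",
                     "ultrasound: %s, FM: %s>\n"),
              x$call_type, x$duration_ms, x$time_to_max_ms,
              x$fundamental_hz, x$dominant_hz, x$n_harmonics,
              x$has_ultrasound, x$fm_pattern))
  invisible(x)
}
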