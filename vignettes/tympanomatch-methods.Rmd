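---
title: "Methods: from synthetic distress calls to tympanic matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from synthetic distress calls to tympanic matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tympanomatch)
```

## The problem

The Weeping lizard (*Liolaemus chiliensis*) is the only member of a very
large iguanid genus known to vocalize: seized individuals emit distress
calls that warn conspecifics of predation risk. Whether such an
evolutionary novelty is tightly matched to the receiver can be asked
quantitatively: how close is the spectrum of the call to the frequency
band where the eardrum vibrates most? This package implements that
analysis chain for two widely separated populations ("central" and
"southern"), working either from recordings or — throughout this vignette
and the test suite — from fully synthetic data, so that every stage has a
known ground truth.

The pipeline has five stages:

1. **Synthesis** — pure-tone stimulus schedules and parametric harmonic
   calls (plus noisy calls and nonlinear-phenomena fixtures).
2. **Call features** — duration, time to maximum amplitude, fundamental
   and dominant frequency, harmonic count, ultrasound flag, FM pattern.
3. **Vibrometry** — from replicated laser-Doppler velocity traces to a
   velocity transfer function and its tympanic summary.
4. **Matching** — zero-lag spectral cross-correlation between call
   spectra and tympanic response spectra; best-frequency mismatch.
5. **Statistics** — chi-square, t tests and two-group stepwise linear
   discriminant analysis for population comparison.

## Synthetic calls

A harmonic call is a phase-coherent stack of `n_harmonics` partials whose
fundamental sweeps linearly between `f0_start_hz` and `f0_end_hz`;
harmonic *k* tracks *k* times the instantaneous fundamental (the phase is
the integral of the instantaneous frequency, so partials never tear) and
is attenuated by `(k - 1) * harmonic_rolloff_db` dB. The two bundled
parameter sets are the population playback calls: six harmonics, 71 ms,
peak at 26 ms, 2.7 → 2.1 kHz (central) and three harmonics, 42 ms, peak
at 19 ms, 6.3 → 5.6 kHz (southern).

```{r}
central <- synthesize_harmonic_call(population_call_params("central"))
call_features(central)
```

Two synthesis choices deserve comment, because the source measurements
were made by eye on oscillograms and spectrograms and an implementation
must commit to operational definitions:

* **Envelope anchoring.** Onset and offset are operationally defined as
  crossings of −20 dB relative to the envelope peak. The amplitude
  envelope is therefore anchored at that floor: a raised-cosine attack
  whose first sample sits exactly at −20 dB and peaks at
  `time_to_max_ms`, then an exponential decay that returns to −20 dB at
  the nominal offset. A raised cosine started from zero instead would put
  the measured onset ~20% of the attack time late and bias both duration
  and time-to-max beyond their ±2 ms tolerances.
* **Harmonic roll-off.** The default 6 dB per harmonic keeps the
  fundamental dominant, as stated for both playback calls. The roll-off
  is recorded in the `call_params` object so tests are self-consistent.

Noisy (non-harmonic) calls are band-limited Gaussian noise whose own
fluctuating envelope is flattened before the nominal envelope is imposed;
without that flattening the measured duration of a 47-ms call wanders by
±3 ms, more than the tolerance of the measurement it is meant to anchor.
Nonlinear-phenomena segments (subharmonics, frequency jumps,
amplitude-modulated broadband "chaos", silence gaps) are fixtures for
exercising detectors, not models of vocal-fold dynamics.

## Feature extraction

* **Duration / time-to-max** come from the smoothed analytic-signal
  envelope (2 ms moving average) and the −20 dB crossings.
* **Dominant frequency** is the global maximum of a Hamming-windowed,
  zero-padded spectrum of a short (3 ms) onset segment. The onset
  segment matters: the playback calls sweep downward at 8.5–16.7 Hz/ms,
  so any window much longer than a few milliseconds reports a dominant
  frequency biased below the nominal onset fundamental by more than one
  43-Hz spectrogram bin. Measuring "at the beginning of the signal" is
  also what the original protocol prescribes.
* **Fundamental** is the best harmonic-comb root explaining the set of
  prominent spectral peaks (approximate GCD), snapped to an exact integer
  divisor of the dominant peak. This is robust when the fundamental is
  weaker than a harmonic.
* **Harmonic count** is the number of comb positions `k * f0` carrying a
  peak at least 10 dB above the spectral median, within a tolerance of 3%
  of the line frequency but never tighter than the analysis main-lobe
  width (a measurement cannot out-resolve its window), and within 35 dB
  of the spectral maximum (the display dynamic range within which a
  spectrogram reader would call a harmonic "recognizable").
* **Call type** uses a frame-wise harmonicity score: per 512-sample frame
  the most plausible comb root is chosen and the score is the fraction of
  frame energy within the comb-line tolerance bands; frames are combined
  weighted by energy. Harmonic calls score ≳ 0.95 even with swept
  fundamentals; turbulent band noise stays ≲ 0.45; the decision threshold
  is 0.5.
* **FM pattern** classifies the autocorrelation-based `f0_track` (with an
  octave-error guard preferring the shortest near-maximal lag) as
  downward, upward, invariant (< 5% relative range), bell or U-shaped;
  the decision is amplitude-invariant and maps downward to upward under
  time reversal.
* **Ultrasound flag**: energy in 20–22 kHz within 30 dB of the dominant
  peak, the operational criterion for calls whose energy ramps gradually
  into the band a 22-kHz-bandwidth recording cannot see.

## Vibrometry

Each stimulus yields a replicate set of velocity traces (20 by default),
spanning the 100-ms tone and an equal silence. Per replicate the SNR is
the RMS of an 80-ms window centered in the tone over the RMS of an 80-ms
window centered in the silence; the `floor(n/4)` lowest-SNR replicates
(the first quartile; 5 of 20) are discarded, ties broken by replicate
order, and the survivors averaged sample-wise. Averaging 15 replicates
improves the SNR by √15, which the test suite verifies by simulation.

The velocity at the stimulus frequency comes from a single 8192-point FFT
centered at the stimulus midpoint (24.41-Hz grid at 200 kHz). Stimulus
frequencies do not generally fall on that grid, and a bare
nearest-bin magnitude can read up to ~36% low from scalloping, so the
readout Hann-windows the segment and recovers the amplitude from the
main-lobe energy around the nearest bin — exact to well under 1% at any
frequency offset, and linear in the trace amplitude. Digital units
convert to m/s through the acquisition chain (5 mm/s per volt vibrometer
sensitivity, 20 dB amplifier gain; `volts_per_unit` covers other
dialects).

Per sound level the velocities form a transfer function; its summary is
the best frequency (argmax; ties to the lowest frequency), the maximum
velocity (also in dB re 1 µm/s), and the half-maximum sensitivity range,
with crossings interpolated linearly between grid points and explicit
edge-clamping flags when the curve never falls below half-maximum inside
the grid. Call-stimulus responses instead use whole-stimulus RMS for the
quartile filter (calls are temporally heterogeneous) and a 2048-point
Welch spectrum (97.66-Hz grid), the smoother analysis appropriate for
spectra that feed the matching statistic.

## The eardrum simulator

The generator stands in for the animals. Each eardrum is a second-order
resonator: velocity gain peaks at `center_frequency_hz`, bandwidth set by
the quality factor, multiplied by a steep (8th-order) low-pass at 13 kHz
that reproduces the observed absence of response above 12–14 kHz, applied
zero-phase in the frequency domain and normalized to unit gain at the
center. Calibration is physical: a tone at the center frequency at 80 dB
SPL produces `peak_velocity_at_80db` (default 1.4 mm/s, the order of the
measured population means of 1.42 and 1.17 mm/s), and the response is
linear in sound pressure, so velocity-vs-SPL has unit slope on the dB
scale. Gaussian noise of fixed standard deviation is added per replicate.

The default quality factor is 4: for this resonator the half-velocity
bandwidth is √3·fc/Q, and Q = 4 near 6 kHz yields the ~2.5-kHz
half-maximum sensitivity ranges characteristic of the recordings
(4.5–7.0 and 5.4–7.9 kHz). Population cohorts draw individual center
frequencies and peak velocities from normal distributions around the
population means (5.78 / 7.17 kHz); the between-individual standard
deviations are not printed anywhere, so the defaults (600 Hz, 0.2 mm/s)
are plausible placeholders and all quantitative tests are
parameter-recovery tests against the generator's own ground truth, never
comparisons to the animals' dispersion.

All randomness flows from one base seed through a documented splitting
scheme (`split_seed(seed, individual, stimulus, replicate)`); each
replicate set draws its noise matrix in one seeded call.

What the simulator does *not* emulate: middle-ear biomechanics (columella
lever, cavity coupling), direction-dependent acoustics, multi-modal
eardrum vibration, or any nonlinearity — it is a phenomenological linear
filter. Passing tests therefore demonstrate that the *analysis chain* is
correct and unbiased for single-peaked linear receivers, not that real
eardrums are such receivers.

## Matching

Spectra are restricted to their common band, linearly resampled onto the
coarser grid, and correlated across frequency bins after mean-centering
and unit-variance scaling — the zero-lag normalized cross-correlation,
identical to a Pearson correlation (verified against `stats::cor` to
1e-12). Linear magnitudes are correlated by default, matching the
power-spectrum framing; a `db` switch enables the dB alternative. The
match table pairs each call's spectrum with the tympanic response evoked
by that call, per individual and sound level, labelled local/non-local by
the individual's population. The scalar mismatch companion is the
absolute difference between tympanic best frequency and call dominant
frequency in kHz (2.68 central vs 1.37 southern for the published
population means).

## Statistics

The chi-square for ultrasound proportions is the plain Pearson statistic
without continuity correction — reconstructing the published 52.16 from
the printed totals (171, 190) and percentages (26.9%, 1.05%) requires the
uncorrected form (Yates gives ≈ 49.6). The t tests default to the
pooled-variance variant, whose df = n1 + n2 − 2 matches the tabulated
df = 36 for cohorts of 12 and 26; Welch is available. The two-group LDA
is Fisher's discriminant with forward stepwise selection minimizing
Wilks' λ (F-to-enter 3.84, the conventional 5% chi-square bound, since
the original procedure names no threshold); for one discriminant function
λ·(1 + eigenvalue) = 1, an identity the suite asserts on every run.
Mixed-effects models, ANCOVA, least-square-means contrasts, outlier
trimming and normality transforms are deliberately out of scope: the
pipeline emits tidy long-format tables that drop straight into lme4-style
model code.

## Numerical choices and degenerate inputs

* WAV I/O is a minimal RIFF reader/writer (16/24-bit PCM, float32 read)
  with symmetric 2^15 scaling, so round trips are exact to quantization;
  clipping input is an error, not a silent truncation.
* The 200-Hz high-pass is a zero-phase 4th-order Butterworth
  (forward–backward), so temporal landmarks are not shifted by group
  delay.
* All-zero calls, zero-variance spectra, disjoint bands, duplicate
  stimulus frequencies, all-zero transfer functions, sub-4 replicate
  sets, and singular within-group scatter all raise immediate errors
  rather than propagating NaN.
* Ties: best-frequency ties resolve to the lowest frequency; quartile
  ties resolve by replicate order; both are deterministic.

## Problem sizes used in the checks

The test suite runs entirely on synthetic data: feature round-trips use
200 randomized in-range parameter sets; classification uses 100 seeded
noisy calls; the end-to-end recovery property uses 200 seeded eardrums
(2–10 kHz) against the 52-frequency portion of the schedule up to 12 kHz
at 80 dB with 20 replicates and 10% trace noise; matching monotonicity
uses 50 seeded runs; the demonstration pipeline uses reduced cohorts.
These sizes were chosen to keep the whole suite within a coffee break on
one core while leaving the statistical margins (≥ 95% criteria) wide.

## Known limitations

* The FM-pattern classifier reproduces the published category system on
  clean contours; it has no confidence measure and inherits any octave
  errors that survive the tracker's guard.
* Nonlinear-phenomena *detection* is not attempted (the original
  classification was visual); only fixture insertion is provided.
* Absolute SPL calibration is represented by a declared reference (94 dB
  SPL ↔ digital full scale); microphone calibration chains are out of
  scope.
* The spectrogram resolution quoted in the source protocol (488 Hz /
  0.256 ms) is inconsistent with a 1024-point FFT at 44.1 kHz; the
  implementation honors FFT length and overlap and lets resolution follow
  from the sample rate.
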