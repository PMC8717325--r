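# tympanomatch

Quantifying the match between acoustic signals and peripheral auditory
sensitivity in the Weeping lizard (*Liolaemus chiliensis*), the only
vocalizing species of its genus. Distress calls warn conspecifics of
predation risk; whether the receiver is tuned to the sender is an open
evolutionary question. This package implements the full analysis chain
used to ask it, for researchers in bioacoustics and sensory ecology:

* **Synthesis** — pure-tone stimulus schedules (0.1 kHz; 0.2–9 kHz in
  0.2-kHz steps; 9.5–20 kHz in 0.5-kHz steps; 22–40 kHz in 2-kHz steps;
  four sound levels) and parametric harmonic calls, including the two
  population-average playback calls (six harmonics, 71 ms, 2.7 → 2.1 kHz;
  three harmonics, 42 ms, 6.3 → 5.6 kHz).
* **Call features** — duration and time to maximum amplitude (−20 dB
  envelope crossings), fundamental and dominant frequency, harmonic
  count, ultrasound flag (20–22 kHz band within 30 dB of the peak),
  harmonic/noisy classification and FM-pattern categories.
* **Vibrometry** — per-replicate stimulus/silence RMS ratios, first-quartile
  discard (5 of 20), sample-wise averaging, single 8192-point FFT velocity
  readout (24.41-Hz grid at 200 kHz), velocity transfer functions per
  sound level, best frequency and half-maximum sensitivity range.
* **Matching** — zero-lag spectral cross-correlation between call spectra
  and tympanic response spectra (a Pearson correlation across frequency
  bins on a common grid), and the best-frequency/dominant-frequency
  mismatch in kHz.
* **Simulator** — a resonant-eardrum model (second-order resonator,
  steep roll-off above 13 kHz, SPL-linear drive, Gaussian trace noise) so
  the entire pipeline runs and is testable without animals.
* **Statistics** — Pearson chi-square without continuity correction,
  pooled/Welch t tests, and two-group stepwise linear discriminant
  analysis with the canonical summary (Wilks' λ, eigenvalue,
  classification rate).

## The statistic at the core

For a call magnitude spectrum $S_c(f)$ and a tympanic response spectrum
$S_t(f)$ on a common frequency grid, the matching statistic is the
zero-lag normalized cross-correlation

$$ r = \frac{\sum_f (S_c(f) - \bar S_c)(S_t(f) - \bar S_t)}
           {\sqrt{\sum_f (S_c(f) - \bar S_c)^2 \sum_f (S_t(f) - \bar S_t)^2}} $$

i.e. the Pearson correlation across bins, computed per individual, sound
level and call origin (local vs non-local). Its scalar companion is the
mismatch distance $|f_{best} - f_{dom}|$ between the eardrum's best
frequency and the call's dominant frequency.

## Worked example

```r
library(tympanomatch)

# the central-population playback call, measured back
call <- synthesize_harmonic_call(population_call_params("central"))
call_features(call)
#> <call_features: harmonic call, 70.9 ms (max at 24.9 ms), f0 2681 Hz,
#>  dominant 2681 Hz, 6 harmonics, ultrasound: FALSE, FM: downward>

# a simulated eardrum tuned near 6 kHz, measured through the full chain
sched <- make_tone_schedule(80)
sched <- sched[sched$frequency_hz <= 12000, ]
drum <- eardrum_model(6000, noise_sd = 0.05)
vels <- sapply(seq_len(nrow(sched)), function(s) {
  reps <- simulate_tone_replicates(drum, sched[s, ], n_reps = 20,
                                   seed = split_seed(1, j = s))
  velocity_at_frequency(filter_and_average(reps), sched$frequency_hz[s])
})
tf <- build_transfer_function(
  data.frame(frequency_hz = sched$frequency_hz, velocity_m_s = vels),
  spl = 80)
summarize_tf(tf)
#> <tympanic_summary: best 6.00 kHz, 1.4 mm/s (62.9 dB re 1 um/s),
#>  range 4.84-7.44 kHz>

# how far is that eardrum from the call?
mismatch_distance(6000, 2681)
#> [1] 3.319
```

The summary reads: the eardrum vibrates fastest at 6.0 kHz (1.4 mm/s at
80 dB SPL, i.e. ~63 dB re 1 µm/s) and moves at least half that fast from
4.8 to 7.4 kHz — while the call's dominant frequency sits 3.3 kHz below
the best frequency, a clear mismatch.

An end-to-end simulated experiment (two cohorts, all stages, CSV/JSON
outputs) is one call:

```r
run_pipeline(pipeline_config(n_central = 2, n_southern = 2,
                             max_freq_hz = 12000, n_reps = 10,
                             seed = 1, out_dir = "out"))
```

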