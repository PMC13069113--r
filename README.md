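# vibci

Analysis toolkit for a gaze-independent brain-computer interface (BCI)
driven by **visual imagery of flickering stimuli**. In classical SSVEP
(steady-state visually evoked potential) BCIs the user fixates a
checkerboard flickering at a known frequency and the occipital EEG locks
to that frequency and its harmonics. Users who cannot control their gaze
— for instance people with locked-in syndrome — cannot use such systems.
The paradigm implemented here replaces perception with imagery: the user
*imagines* one of two flickering checkerboards, which produces
SSVEP-like spectral peaks of lower amplitude, spread around the imagined
frequency, and a 3-class linear decoder (low frequency, rest, high
frequency) turns that activity into commands.

The package is aimed at BCI methods researchers: it contains a
protocol-faithful synthetic EEG generator, so every stage of the
analysis is testable end to end without any recorded data, plus the full
decoding and evaluation pipeline.

## What it implements

* **Synthetic sessions** — 10-channel EEG (O2, O1, Pz, P3, P4, Oz, T7,
  P7, AF4, F8) as Gaussian 1/f<sup>α</sup> background plus, during task
  events, sinusoids at the class frequency f and its second harmonic 2f,
  occipitally weighted; imagery events are attenuated and frequency
  jittered. Four protocol steps: SSVEP calibration (5/7/9/12 Hz + rest,
  15 × 3 s), mixed training, 10 offline imagery recordings (3 classes ×
  20 × 9 s), and one fixed-sequence online session (20 × 5 s).
* **Preprocessing** — 60 Hz low-pass, 48–52 Hz notch, 3–36 Hz 8th-order
  Butterworth band-pass (zero-phase), then step-specific epoch windows
  ([1.8, 2.8) s for calibration, [1, 7) s offline, [1, 4) s online).
* **Spectral features** — Welch PSD with 2-s Hamming segments and 50%
  overlap, restricted to [3, 36] Hz and concatenated over the 10
  electrodes (670 features per trial).
* **Frequency selection** — each candidate frequency f is scored from
  occipital calibration PSDs by a peak-sharpness statistic: with
  Δp<sub>±</sub>(f) = M<sub>±</sub>(f) − m<sub>±</sub>(f), where
  M<sub>±</sub> is the PSD maximum within ±0.05 Hz of the peak (per
  side) and m<sub>±</sub> the minimum within ±0.5 Hz,

  S = max(Δp<sub>+</sub>(f), Δp<sub>−</sub>(f)) / ι,

  with ι the width of the peak at half height. Scores at f and 2f are
  summed over repetitions and over Oz/O1/O2; the two highest-scoring,
  harmonically non-conflicting candidates become the subject's primary
  frequency couple.
* **Decoding** — one-vs-rest linear SVM (C = 1) on standardized PSD
  features; 5-fold *temporal* cross-validation over the 10 offline
  recordings (consecutive pairs held out); the best fold's model is
  replayed against the online session.
* **Statistical evaluation** — adjusted-Wald (Agresti–Coull) upper
  confidence bounds for the accuracy of a random k-class classifier,
  population-SD accuracy summaries, and Welch's t-test with
  Welch–Satterthwaite degrees of freedom, evaluated against bundled
  per-subject reference accuracy tables from a published 20-subject
  study.

## Worked example

Simulate a calibration session for one synthetic subject, score the
candidate frequencies, and select the couple:

```r
library(vibci)
profile <- make_subject_profile(seed = 42)
p1 <- protocol_spec(1)
rec <- filter_chain(simulate_recording(p1, profile, seed = 43, fs = 256))
rec
#> <eeg_recording> 10 channels x 57600 samples @ 256 Hz (225.0 s)
#>   channels: O2, O1, Pz, P3, P4, Oz, T7, P7, AF4, F8
#>   annotations: 75 events (rest: 15, ssvep_12: 15, ssvep_5: 15, ssvep_7: 15, ssvep_9: 15)

scores <- score_candidates(extract_epochs(rec, p1))
scores
#> <freq_scores> candidate totals:
#>      5 Hz: 27.4
#>      7 Hz: 10.29
#>      9 Hz: 21.86
#>     12 Hz: 6.998
select_couple(scores)
#> <freq_couple> (5 Hz, 9 Hz)
```

The totals are summed peak-sharpness scores; 5 and 9 Hz win because this
profile responds most strongly there, so the subject will imagine 5 Hz
and 9 Hz flicker for the rest of the session. `run_pipeline()` chains
every stage (calibration → couple selection → offline cross-validation →
online replay → chance statistics) into one deterministic report, and
the reference-table evaluation reproduces the published summary
statistics:

```r
ta <- subject_accuracies()
summarize_accuracies(ta$offline_mean)$mean   # 60.925  -> offline mean accuracy (%)
onl <- summarize_accuracies(ta$online)       # mean 50.67, population SD 8.62
welch_t(onl$mean, onl$sd, 20, 33.33, 26.05, 20)
#> <welch_result> t = 2.825, df = 23.11, p = 0.009569
chance_upper_bound(160, 3, 0.01)$bound       # 39.07 % (99% bound, offline design)
```

An observed accuracy above the 39.0% bound cannot plausibly come from a
guessing classifier; all 20 reference subjects exceed it
(`count_above(ta$offline_mean, 39.00)` is 20).

A thin command-line front end (`inst/cli/vibci.R`) exposes `simulate`,
`pipeline` and `stats` subcommands over the same functions.

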