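---
title: "Models and methods behind vibci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vibci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibci)
```

## The paradigm

vibci models a gaze-independent brain-computer interface in which the
user *imagines* a checkerboard flickering at one of two
subject-specific frequencies. Imagined flicker produces occipital
spectral peaks resembling steady-state visually evoked potentials
(SSVEPs) but weaker and broader. The analysis proceeds in four protocol
steps: an SSVEP calibration session used to select the subject's two
best frequencies from the candidate set {5, 7, 9, 12} Hz; a mixed
familiarization session; ten offline imagery recordings that train a
3-class decoder (low frequency, rest, high frequency); and one
fixed-sequence online session decoded by the best cross-validation
fold's model.

## The synthetic EEG generator

Because no public recordings accompany the paradigm, the package ships
a generator whose output exercises every downstream stage.

Each channel carries a Gaussian $1/f^{\alpha}$ background synthesized
in the frequency domain (coefficients with power $\propto k^{-\alpha}$,
random phases), standardized to `noise_scale` µV RMS and multiplied by
a per-channel spatial gain. During a non-rest event the channel
additionally receives

$$a\,g_c\,[\sin(2\pi f t + \phi_1) + r \sin(2\pi\,2f\,t + \phi_2)]$$

where $a$ is the subject's response gain at the class frequency $f$
(µV), $g_c$ the spatial gain, $r$ the harmonic ratio, and
$\phi_1, \phi_2$ random phases per event. Imagery events differ from
perception events in two ways, reproducing the qualitative structure of
imagined-flicker spectra: the amplitude is multiplied by
`vi_attenuation` and the event frequency is offset by a per-event draw
from $N(0, \texttt{vi\_jitter\_sd}^2)$, which smears the
session-averaged peak.

Defaults, fixed once and used throughout:

| parameter | default | units | rationale |
|---|---|---|---|
| `fs` | 256 | Hz | typical for research-grade biosignal amplifiers; any value > 120 Hz works |
| `response_gain` | 2.0 / 1.2 / 1.8 / 1.0 at 5/7/9/12 Hz | µV | low-µV evoked amplitudes over a ~1 µV background; distinct so a couple exists |
| `harmonic_ratio` | 0.3 | – | second harmonics present but weak |
| `spatial_gain` | 1 occipital, 0.5 parietal, 0.25 frontal/temporal | – | occipitally dominant response and background |
| `vi_attenuation` | 0.5 | – | imagery peaks roughly half the evoked amplitude |
| `vi_jitter_sd` | 0.1 | Hz | event-to-event smearing of the imagined frequency |
| `noise_exponent` α | 1.0 | – | canonical 1/f EEG background |
| `noise_scale` | 1.0 | µV RMS | sets SNR ≈ 1–2 at the occiput |

The generator emulates: 1/f background, narrowband responses with
second harmonics, occipital dominance, lower and broader imagery peaks,
and the exact protocol timing (15 × 3 s calibration events; 60 offline
events of 9 s totalling 540 s per recording; 60 online events of 5 s
totalling 300 s, in the fixed order low/rest/high repeated). It does
*not* emulate eye-blink or muscle artifacts, electrode drift,
non-stationarity within events, inter-subject anatomical variability,
or any biophysical forward model, and the two-minute rests between
recordings are omitted as carrying no signal of interest. Passing tests
on synthetic data therefore demonstrate the *pipeline's* correctness
and statistical honesty, not expected performance on real EEG — real
per-subject accuracies depend on effects the generator deliberately
leaves out.

## Preprocessing

The offline filter chain applies, in order, a 60 Hz low-pass (4th-order
Butterworth), a 48–52 Hz notch (2nd-order IIR biquad, −3 dB bandwidth
4 Hz, bilinear design), and the 3–36 Hz 8th-order Butterworth band-pass.
Only the band edges and the band-pass order are dictated by the
acquisition description; the low-pass/notch orders are the conventional
minimal designs. All three run forward–backward (`signal::filtfilt`),
i.e. zero phase: the analysis is offline, and zero-phase application
keeps event onsets aligned between raw and filtered signals. A
consequence is that the effective attenuation is the squared magnitude
response of each design.

Epochs use seconds from event onset, half-open windows $[t_0, t_1)$,
and sample index $\lfloor t f_s \rfloor$, so no boundary sample is
counted twice: [1.8, 2.8) s for calibration events, [1, 7) s offline,
[1, 4) s online.

## Spectral estimation

Two estimators are used, both Hamming-windowed, one-sided,
density-scaled (µV²/Hz):

* `welch_psd()` — Welch's method with 2-s segments and 50% overlap, the
  convention used for classifier features; the grid spacing is fixed at
  0.5 Hz by the segment length regardless of epoch duration (5 averaged
  segments for 6-s epochs, 2 for 3-s epochs).
* `highres_psd()` — a single zero-padded periodogram on a requested
  grid (default 0.025 Hz), used by the frequency scorer, whose
  ±0.05 Hz neighbourhoods are finer than the native resolution of a
  1-s calibration epoch.

Feature vectors take the Welch PSD at the closed band [3, 36] Hz — 67
bins at 0.5 Hz — per electrode, concatenated electrode-major over the
ten analysis channels (670 columns). A scalar band-average per
electrode was rejected: it would make the two imagery classes nearly
indistinguishable by construction. The Welch scaling convention is
immaterial downstream because features are standardized per column
before classification.

## Frequency scoring

For a peak at $f$, each side's prominence is
$\Delta p_{\pm}(f) = M_{\pm}(f) - m_{\pm}(f)$, with $M_{\pm}$ the PSD
maximum within 0.05 Hz of $f$ on that side and $m_{\pm}$ the minimum
within 0.5 Hz; both windows share the centre point, anchoring each side
at the apex. The score is
$S = \max(\Delta p_{+}, \Delta p_{-}) / \iota$ with $\iota$ the width
of the peak at half its height: apex within ±0.05 Hz, half-height
crossings found outward from the apex by linear interpolation within
±0.5 Hz, clamped at the window edge when a side never crosses, and
floored at one grid step so a degenerate single-bin peak cannot divide
by zero. Scores at $f$ and $2f$ are summed (equal weight), then over
the three occipital electrodes (plain sum; no combination rule is
dictated beyond naming the electrodes), then over the 15 repetitions of
each candidate's class. Rest epochs contribute nothing — no baseline
correction is applied. The top two totals form the couple, with ties
broken toward the lower frequency and a harmonic-conflict rule
(|2·f_low − f_high| ≤ 0.25 Hz) that replaces the lower-scoring member;
within {5, 7, 9, 12} Hz every pair is conflict-free, so the rule only
matters for user-supplied candidate sets or tolerances.

A property worth knowing: $S$ is amplitude-proportional, and a
$1/f^{\alpha}$ background has both more power and larger absolute
fluctuations at low frequencies. Under the *null* (no planted response)
the score totals are therefore systematically larger for 5 and 7 Hz
than for 9 and 12 Hz, and the selected "couple" concentrates on
(5, 7) rather than spreading uniformly — the test suite documents this
directly. With realistic planted responses the bias is negligible (the
planted couple is recovered in 100/100 seeded runs), but zero-signal
subjects do not produce uniformly random couples, and users comparing
empirical couple distributions against chance should keep that in mind.

## Decoding and validation

The decoder standardizes each feature column with the training rows'
mean and SD (zero-variance columns get scale 1), then fits one
linear-kernel SVM (C = 1, `e1071`/libsvm) per class one-vs-rest,
predicting the class with the largest decision value; decision-value
signs are normalized against libsvm's label-order dependence. C and the
one-vs-rest topology are fixed, not tuned — the aim is a reproducible
reference decoder, not a maximized score.

Temporal cross-validation groups the ten chronologically ordered
offline recordings into five consecutive pairs; fold *i* tests on pair
*i* and trains on the remaining eight recordings. This is the only
layout consistent with both "temporal" and "two of the recordings
swapped with the test set per iteration". Whole recordings are held
out, never trials, so no within-recording leakage can occur;
standardization parameters come from training folds only (a property
the tests check by deleting test rows). Fold-level accuracy summaries
report the population SD across the five folds. The online model is
the best fold's, earliest fold on ties. The familiarization step's
recordings are never used for training.

## Evaluation statistics

The chance bound for a k-class random classifier over n = k·(trials
per class) balanced trials is the adjusted-Wald (Agresti–Coull) upper
limit at level α: with $z = \Phi^{-1}(1-\alpha/2)$,
$\tilde n = n + z^2$, $\tilde p = (n/k + z^2/2)/\tilde n$, the bound is
$100(\tilde p + z\sqrt{\tilde p(1-\tilde p)/\tilde n})$ percent. This
construction reproduces the reference values 39.0% (99%, 160
trials/class), 37.7% (95%), and 50% (99%, 20 trials/class) to within
0.1 points; the reference's fourth value, 45% (95%, 20 trials/class),
is *not* reproduced (the construction yields ≈ 46.0) and is excluded
from the package's checks.

Accuracy summaries use the population (divisor-n) standard deviation —
the only convention that reproduces the reference online-column SD of
8.62. The Welch t statistic from group summaries uses sample variances
($s_i^2/n_i$) and Welch–Satterthwaite degrees of freedom; against the
cited random-distribution summary (mean 33.33, SD 26.05, n 20) the
online column gives t = 2.82, df = 23.1. The reference pair is not
exactly attainable under any single variance convention (population-SD
inputs give 2.83/23.1, sample-SD 2.82/23.3), so the checks carry
tolerances of ±0.05 on t and ±0.3 on df. The SD 26.05 of the random
distribution is treated as a cited constant, not recomputed. The
bundled tables also show a small internal inconsistency in their
source: direct counts over the online column give 8 subjects strictly
above 50% and 14 strictly above 45%, versus the prose's 9 and 16;
`count_above()` reports the direct counts.

## Problem sizes in the test suite

The statistical property checks simulate at fs = 128 Hz and, for the
decoder-honesty Monte Carlo, with 5 repetitions per class per offline
recording — sizes chosen so the full suite runs on a desk machine in
minutes. The properties checked (chance-level behaviour, planted-couple
recovery, permutation honesty) are invariant to these sizes; the
calibration protocol itself (15 repetitions, 5 classes) is always
simulated at full size. All Monte-Carlo assertions in the tests state
their seed counts explicitly (typically 100).

## Known limitations

* The synthetic generator's stationary, artifact-free events make
  decoding easier than real EEG; its accuracies say nothing about
  attainable real-subject performance.
* The peak score's low-frequency bias under 1/f backgrounds (above)
  means null couples are not uniform.
* The EDF+ writer/reader covers the subset this package produces
  (16-bit, equal channel rates, 1-s records, TAL annotations); it is
  not a general EDF parser.
* No artifact rejection, re-referencing, or channel interpolation is
  implemented — the modelled analysis performs none.
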