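---
title: "Pupillary and microsaccadic measures of cognitive effort: models and design"
author: "oculoeffort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupillary and microsaccadic measures of cognitive effort: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`oculoeffort` analyses binocular eye-tracking recordings from a sequential
cue-acquisition decision task: on each trial a participant, primed with a
neutral, aversive or erotic image, acquires between one and six cues (ordered
by validity) before choosing between two alternatives. The number of acquired
cues indexes pre-decisional cognitive effort. Two families of oculomotor
measures are extracted per cue epoch and analysed:

* **Pupillary.** BCPD (baseline change in pupil diameter): the mean smoothed
  pupil during an epoch minus a baseline taken as the mean smoothed pupil over
  the participant's training trials; positive values mean dilation. LHIPA
  (Low/High Index of Pupillary Activity): the duration-normalised count of
  thresholded modulus maxima of the ratio between low- and high-frequency
  wavelet detail coefficients of the epoch's pupil trace.
* **Microsaccadic.** Event rate (events/s) and mean magnitude (degrees) of
  microsaccades detected within fixations by a velocity-threshold detector,
  validated against the main sequence (the linear law
  `peak velocity = a * magnitude + b`).

Each trial is summarised by differential measures,
`Δm = m(last cue epoch) − m(first cue epoch)`, and the trial-level table is
analysed with nested linear mixed models: random intercepts for experimental
condition and for participants nested in condition, fixed effects
`condition * n_cues` with treatment coding (neutral reference), maximum
likelihood estimation, a likelihood-ratio test of the full against the
intercept-only model, and pseudo-R² (total) defined as the squared
correlation between fitted and observed values. Wald t statistics carry
Satterthwaite degrees of freedom.

Single-cue trials are retained with all deltas exactly zero (last epoch =
first epoch): the cue-count regressor spans 1–6, so the analysis rows at
`n_cues = 1` must exist, and the identity of the two epochs forces the zero.

## The processing chain

1. **Blink handling.** Maximal runs of missing pupil in either eye, padded by
   100 ms per side (the lid-closure artifact outlasts the missing samples)
   and merged when overlapping, are masked to missing in all channels.
2. **Binocular averaging.** `(x, y) = ((xl + xr)/2, (yl + yr)/2)`, with a
   single-eye fallback when exactly one eye is missing; pupil is averaged
   identically. All later stages run on this cyclopean signal.
3. **Unit conversion.** Pixels to degrees about the screen centre,
   `deg = atan2(offset_cm, distance_cm) * 180/π` per axis. The physical
   screen size must be stated explicitly in the configuration; it is never
   inferred from a monitor diagonal.
4. **Pupil smoothing.** 100 ms centred moving average ignoring missing
   samples (window exposed in the configuration). BCPD uses the smoothed
   signal; LHIPA deliberately uses the unsmoothed cyclopean pupil, because a
   100 ms average removes exactly the high-frequency band the index measures.
5. **Fixation segmentation.** Dispersion-threshold identification (I-DT):
   maximal windows whose dispersion (max − min summed over the two axes)
   stays within 1.0° and that last at least 100 ms; blink gaps terminate
   fixations. A dispersion detector fits a task whose stimuli are static;
   both thresholds are configuration knobs.
6. **Microsaccade detection** within each fixation: five-point velocity
   estimate `v_n = (x_{n+2} + x_{n+1} − x_{n−1} − x_{n−2}) / (6 dt)`;
   per-axis robust noise scale `σ_a = sqrt(median(v_a²) − median(v_a)²)`
   (which converges to 0.6745 times the SD for Gaussian noise — the constant
   is absorbed by the multiplier); elliptic criterion
   `(vx/ησx)² + (vy/ησy)² > 1` with `η = λσ`, λ = 6; candidate runs of at
   least 6 ms become events; events closer than 20 ms merge; events larger
   than 1.0° are discarded. Magnitude is the start-to-end displacement of the
   detected event (not the peak-to-peak excursion — conventions differ across
   the literature and this one is pinned). Thresholds are estimated per
   fixation when it offers at least 50 defined velocity samples, otherwise
   pooled over the trial's fixations.

## The synthetic experiment generator

No recordings ship with the package; `generate_dataset()` produces complete
experiments with the behavioural and signal structure the analysis assumes,
plus a ground-truth ledger (every injected event, every latent epoch mean)
so that the whole pipeline is validated by parameter recovery.

Study conditions baked into the defaults: 8/7/6 participants in the
neutral/aversive/erotic conditions; 3 training plus 24 main trials each;
fixation 1000 ms, affective prime 3000 ms, first cue epoch exactly 2000 ms,
later epochs self-paced and drawn lognormal (mean 1500 ms, SD 500 ms — the
study reports no per-epoch durations, so this is an explicit stand-in);
per-condition cue-count distributions with the bimodal single-cue/five-cue
structure; microsaccade rate 2.0 events/s at cue 1 with per-cue slopes
−0.355 (neutral), −0.657 (aversive), −0.355 (erotic), floored at
0.05 events/s; main sequence slope 376.37 1/s, intercept 12.91 deg/s; evoked
pupil dilation slopes +37.00 / +98.79 / −28.86 units per additional cue for
neutral / aversive / erotic; participant pupil baselines
N(4000, 128.6²) in arbitrary tracker units (the baseline mean sets BCPD
values of order 100); hippus as a 0.2 Hz sinusoid of amplitude 30 with
random phase; high-frequency pupil noise with SD 50 + 10·(cue − 1);
blinks as a 0.1/s Poisson process of 150 ms missing runs. Training trials
hold the cue index at 1 with no evoked dilation: they define the baseline.

Design choices worth spelling out:

* **Overshooting waveforms are forced by the main sequence.** The five-point
  estimator's output on a monotone displacement pulse of size A is bounded by
  `A/(3 dt)` ≈ 333·A at 1 kHz, below the target line `376·A + 12.9`. Any
  generator whose detected events are to lie on that line must therefore
  produce saccades with dynamic overshoot — the excursion exceeds the net
  displacement — which is also what real microsaccades do. Each event is a
  minimum-jerk main pulse to `A(1+β)` followed by a return of `βA`, with β
  solved per event (a one-dimensional linear max-equation over the filtered
  template) so the noise-free filtered peak speed equals the target exactly.
  Slow events (below the line for their size) get a longer main phase instead
  of a vanishing overshoot, mirroring the duration–velocity trade-off of real
  saccades and keeping the detected run above the detector's minimum
  duration.
* **Curvature bridges the reversal.** The filtered speed along the saccade
  axis necessarily dips to zero between excursion peak and return. A zero-net
  orthogonal excursion (trajectory curvature, as in real saccades) spanning
  the reversal keeps the elliptic criterion satisfied, so the detector sees
  one contiguous event covering the full excursion and return — otherwise the
  event would fragment below the minimum duration or end at the overshoot
  peak with an inflated magnitude.
* **Events re-centre gaze.** Directions are biased toward the current offset
  from fixation centre (square-wave-like alternation), and each placement is
  checked against a running dispersion budget of 0.88° for the current
  inter-blink segment, re-drawing the direction — in rare cases shrinking the
  event — rather than ever rejecting it (rejection would thin the event rate
  and bias rate recovery). Fixational eye movements are, by definition,
  movements that do not leave fixation.
* **Rates are realised on visible time.** Event onsets follow a renewal
  process with a 60 ms refractory period whose expected rate matches the
  nominal rate exactly; the process is laid out on blink-free time at
  compensated intensity, so the measured rate per second of epoch is unbiased
  with respect to the generator's rate even though no events are injected
  into masked windows. The recording extends 150 ms past the last cue offset
  (a response interval) so events near the final boundary complete.
* **Magnitudes** are lognormal (median 0.22°, log-SD 0.35), truncated to
  [0.12°, 0.42°]: the lower cut keeps events above the detection floor, the
  upper cut keeps excursions inside the I-DT dispersion window so events are
  not cut in half by fixation boundaries.
* **Noise calibration.** Per-eye measurement noise (0.005° SD) and
  mean-reverting drift (innovation 0.0015°/sample, AR coefficient 0.995) sit
  at the clean end of video-tracker performance so that injected events of
  0.12° and larger stay above the detection floor; velocity noise about the
  main sequence (SD 8 deg/s) is calibrated so the detected-event
  main-sequence R² lands in [0.8, 0.9]. Per-eye pupil noise is a fixed
  2-unit SD.
* **Behavioural outcomes are cosmetic.** Choice is uniform and accuracy is
  Bernoulli at the first cue's validity; nothing downstream analyses them.

What the generator does **not** emulate: ocular tremor, inter-region
saccades (cue reading is collapsed into fixational behaviour), pupil
foreshortening or gaze-position artifacts, luminance responses, and any
dependence of pupil noise colour on arousal. Passing recovery tests therefore
demonstrates that the pipeline measures what the generator encodes — not that
real recordings satisfy the generator's assumptions.

## LHIPA internals and an honest caveat

The index follows its defining construction: periodized discrete wavelet
transform with Symlet-16 analysis filters (implemented in the package as a
plain pyramid cascade and verified against an independent wavelet library on
frozen fixtures); high-frequency band at level 1; low-frequency band at half
the maximal decomposition depth for the slice length; both coefficient sets
amplitude-normalised by `2^(level/2)`; the sparser low-frequency
coefficients aligned to the high-frequency grid by index striding; modulus
maxima (samples whose absolute ratio strictly exceeds both neighbours);
universal threshold `σ̂ sqrt(2 log n)` with σ̂ the SD of the maxima series,
*keeping* maxima at or below the threshold (suppression of large-amplitude
artifacts); count divided by slice duration. Missing samples are linearly
interpolated first; slices over 30% missing give NA with a warning.

Two properties follow directly and are enforced by tests: the index halves
when the slice duration doubles at a fixed surviving-maxima count, and it is
invariant to amplitude rescaling (the threshold scales with the series).

A third, often-expected property — that the index *decreases* when
high-frequency content increases — does **not** hold for stationary noise,
and the package does not pretend otherwise. At a 1000 Hz sampling rate and
2 s epochs the two bands sit at 62–125 Hz and 250–500 Hz, far above any
pupillary physiology, and rescaling stationary noise rescales the ratio
series as a whole; every statistic of a series that is thresholded by its
own spread is then invariant in distribution. Monte-Carlo over white, bursty
and heteroscedastic high-frequency noise confirms the insensitivity for this
implementation and for an independent re-implementation alike. This matches
the null LHIPA findings in the kind of study the pipeline targets. The
predecessor index (IPA) is not implemented; the `pupil_index_config()`
surface is the extension point.

## Statistical layer

Correlations are zero-order Pearson tests on participant-level means
(`t = r sqrt(n−2)/sqrt(1−r²)`, two-sided). Cue-count distributions are
tested per condition against equal proportions over the six possible counts
with `χ² = Σ (O−E)²/E`, df = 5. Mixed models delegate to `lme4` /
`lmerTest` (maximum likelihood; Satterthwaite t); with only three condition
levels the condition-level variance component is weakly identified, may
legitimately be estimated as zero, and is reported but never tested. The
microsaccade-rate model uses the per-trial delta as its dependent variable
by default; per-epoch raw rates are available through
`run_pipeline(..., ms_rate_dv = "epoch")`. Two-sided p-values at α = 0.05
throughout, no multiplicity correction.

Degenerate inputs are explicit errors, never silent zeros: zero-variance
correlation input, zero expected counts (structural-zero bins must be
dropped by the caller), constant regression designs, under-populated
conditions (fewer than two participants), and pupil slices too short for
two separated decomposition levels.

## Problem sizes and reproducibility

All validation runs on synthetic data at the study's own design size
(21 participants, 504 main trials, ~2.5 M samples per experiment). The test
suite uses one cached default experiment for structural checks; ten
experiments for rate recovery; fifty for effect-size recovery (the slopes
37.00 units/cue and −0.355 events/s per cue must land within two estimated
standard errors of the estimate in at least 90% of runs) and fifty
null experiments at the same size for the likelihood-ratio false-positive
rate. A caveat discovered during that calibration: because single-cue trials
carry deltas that are exactly zero by construction, the delta tables are
structurally heteroscedastic and the ML likelihood-ratio test is mildly
anticonservative (about 7-8% rejections at nominal 5% in direct null
simulation at the default design size, versus 4.8% with the structural zeros
removed) — inference on delta measures near the significance boundary should
be read with that in mind. The acceptance script re-derives the headline quantities from
scratch: the detection-recovered main-sequence slope at ≥ 10⁴ events under
low velocity noise, the single-cue and five-cue percentages at 10⁵ draws,
and the mean recovered ΔBCPD cue slope over 50 experiments. Every random
stage is seeded; a seed fully determines a dataset, byte for byte.

## Known limitations

* The generator's saccade waveform is one convenient member of the family
  satisfying the magnitude/peak-velocity contract; no claim is made about
  real waveform shape, and waveform-sensitive statistics (e.g. acceleration
  profiles) should not be read off the synthetic traces.
* Detected event rates run ~2–5% below nominal in late epochs of long trials
  (fixation-boundary and short-segment losses); the delta-based analyses are
  insensitive to the shared component of this loss.
* LHIPA at 1 kHz / 2 s epochs indexes tracker-noise bands (see above); its
  mixed-model results on synthetic data mostly reflect epoch-length
  structure, not effort.
* The I-DT implementation is greedy and order-dependent by construction (as
  is the classic algorithm); ties at the dispersion threshold resolve in
  favour of the earlier, longer fixation.
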