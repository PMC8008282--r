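# oculoeffort

Pupillary and microsaccadic measures of cognitive effort under affective
priming.

## The problem

In sequential cue-based decision making, the number of cues a person acquires
before deciding indexes pre-decisional cognitive effort: one-cue decisions
point to a fast one-reason heuristic (Take The Best), many-cue decisions to a
compensatory weighted-additive strategy. Two oculomotor systems track that
effort. The pupil dilates with load: the package measures **BCPD** (baseline
change in pupil diameter), the mean smoothed pupil during a cue epoch minus a
baseline taken from the session's training trials, and **LHIPA** (Low/High
Index of Pupillary Activity), a wavelet index of pupil oscillatory structure.
Microsaccades — involuntary fixational saccades below ~1°, about 1–2 per
second — are inhibited by load: the package measures their **rate** and
**magnitude** per cue epoch, after validating detected events against the
main sequence, the linear law

```
peak velocity = a * magnitude + b        (a in 1/s, b in deg/s)
```

Detection is the classic velocity-threshold scheme: a five-point digital
derivative `v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)` on the
binocularly averaged gaze, per-axis median-based noise scales
`sigma = sqrt(median(v^2) - median(v)^2)`, and the elliptic criterion
`(vx/(lambda sx))^2 + (vy/(lambda sy))^2 > 1` with `lambda = 6`, within
I-DT fixations. Per-trial differential measures
`Δm = m(last cue epoch) − m(first cue epoch)` feed nested linear mixed
models (random intercepts for condition and participants nested in
condition; fixed effects `condition * n_cues`, neutral reference; ML
estimation, likelihood-ratio tests, pseudo-R²).

Because no recordings ship with the package, a first-class synthetic
generator reproduces the experiment — 21 participants in three affective
priming conditions (neutral/aversive/erotic, 8/7/6), 3 training plus 24 main
trials each at 1000 Hz — with the cue-acquisition distribution, a
main-sequence-true microsaccade process and condition-specific evoked pupil
dilation built in, plus a ground-truth ledger for parameter-recovery
validation. See the methods vignette
(`vignettes/oculoeffort-methods.Rmd`) for the full model and design
rationale.

## Worked example

```r
library(oculoeffort)

ds  <- generate_dataset(simulation_config(seed = 3))
rep <- run_pipeline(dataset = ds)

rep$main_sequence
rep$lmms$d_bcpd
rep$correlations$ms_rate_vs_cues
```

prints (elided):

```
Main sequence: peak velocity = 358.48 * magnitude + 16.77
  n = 3155 events, R^2 = 0.870, slope SE = 2.471

Nested LMM for d_bcpd (n = 504 rows)
  LRT full vs null: chi^2(5) = 1885.641, p = 0; pseudo-R2 (total) = 0.982
  variance components: condition 0.000, participant 1.575, residual 306.902
  (Intercept)                  b =   -37.216  SE =    2.404  t(157.0) = -15.479  p = 0.0000
  conditionaversive            b =   -59.612  SE =    3.347  t(138.3) = -17.811  p = 0.0000
  conditionerotic              b =    64.252  SE =    3.520  t(140.1) = 18.253  p = 0.0000
  n_cues                       b =    37.132  SE =    0.691  t(504.0) = 53.768  p = 0.0000
  conditionaversive:n_cues     b =    60.205  SE =    1.029  t(503.2) = 58.485  p = 0.0000
  conditionerotic:n_cues       b =   -64.673  SE =    1.125  t(503.8) = -57.491  p = 0.0000

r = -0.226, t(19) = -1.009, p = 0.3255
```

Reading the output: detected microsaccades fall on a steep, tight main
sequence (slope 358.5 1/s against the generator's 376.37, R² 0.87 —
detection recovers the injected law up to a small measurement attenuation);
the ΔBCPD mixed model recovers the generator's evoked-dilation slopes
(37.13 vs 37.00 units/cue in the neutral reference, +60.2 aversive and
−64.7 erotic interaction offsets vs the generator's +61.79/−65.86); and the
participant-level correlation between microsaccade rate and the number of
acquired cues is negative (rate inhibition under effort), though not
significant at n = 21 participants in this run.

`write_report(rep, "out/")` emits `cue_distribution.csv`,
`correlations.csv`, `main_sequence.csv`, one `lmm_<dv>.csv` per model, the
epoch-metric and delta tables, and `summary.json`. A thin command-line
wrapper lives in `inst/cli/oculoeffort`:

```sh
Rscript inst/cli/oculoeffort simulate --seed 3 --out data/
Rscript inst/cli/oculoeffort run --seed 3 --out report/
```

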