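# Shared fixtures and independent oracles. The default synthetic dataset and
# its pipeline report are expensive, so they are built once per test run and
# reused across files.

.oe_cache <- new.env(parent = emptyenv())

cached_dataset <- function() {
  if (is.null(.oe_cache$ds))
    .oe_cache$ds <- generate_dataset(simulation_config(seed = 42))
  .oe_cache$ds
}

cached_report <- function() {
  if (is.null(.oe_cache$report))
    .oe_cache$report <- run_pipeline(dataset = cached_dataset())
  .oe_cache$report
}

# tiny reduced design used where a full experiment is unnecessary
small_config <- function(seed = 7, effects = effect_params()) {
  simulation_config(
    n_participants_per_condition = c(neutral = 1L, aversive = 1L, erotic = 1L),
    task = task_spec(n_trials = 4L), effects = effects, seed = seed)
}

flat_recording <- function(n = 300, participant = "P01", trial = 1L,
                           pupil = 4000, x = 512, y = 384) {
  t <- 0:(n - 1)
  gaze_recording(participant, trial, t,
                 xl = rep(x, n), yl = rep(y, n), xr = rep(x, n), yr = rep(y, n),
                 pl = rep(pupil, n), pr = rep(pupil, n))
}

# Exhaustive-scan I-DT oracle: dumb greedy with full dispersion recomputation
# at every step. Used to pin the optimised implementation.
idt_oracle <- function(t, x, y, cfg, dt_ms = 1) {
  w <- max(2L, as.integer(round(cfg$fixation_min_dur_ms / dt_ms)))
  theta <- cfg$fixation_dispersion_deg
  disp <- function(idx) (max(x[idx]) - min(x[idx])) + (max(y[idx]) - min(y[idx]))
  valid <- !is.na(x) & !is.na(y)
  segs <- oculoeffort:::true_runs(valid)
  out <- list()
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, "start"]; b <- segs[s, "end"]
    i <- a
    while (i + w - 1L <= b) {
      if (disp(i:(i + w - 1L)) > theta) {
        i <- i + 1L
        next
      }
      e <- i + w - 1L
      while (e + 1L <= b && disp(i:(e + 1L)) <= theta) e <- e + 1L
      out[[length(out) + 1L]] <- c(start_idx = i, end_idx = e)
      i <- e + 1L
    }
  }
  if (length(out)) as.data.frame(do.call(rbind, out))
  else data.frame(start_idx = integer(), end_idx = integer())
}

# Brute-force microsaccade detector: literal five-point formula per sample,
# explicit run scan and merge loop. Independent of the package internals.
ms_oracle <- function(x, y, dt, cfg, thresholds) {
  n <- length(x)
  vx <- vy <- rep(NA_real_, n)
  for (i in 3:(n - 2)) {
    vx[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
    vy[i] <- (y[i + 2] + y[i + 1] - y[i - 1] - y[i - 2]) / (6 * dt)
  }
  crit <- (vx / thresholds[["eta_x"]])^2 + (vy / thresholds[["eta_y"]])^2 > 1
  crit[is.na(crit)] <- FALSE
  runs <- list(); start <- NA
  for (i in seq_len(n)) {
    if (crit[i] && is.na(start)) start <- i
    if ((!crit[i] || i == n) && !is.na(start)) {
      end <- if (crit[i]) i else i - 1L
      runs[[length(runs) + 1L]] <- c(start, end)
      start <- NA
    }
  }
  min_len <- ceiling(cfg$min_dur_ms / (dt * 1000))
  runs <- Filter(function(r) r[2] - r[1] + 1L >= min_len, runs)
  if (!length(runs))
    return(data.frame(onset_idx = integer(), offset_idx = integer()))
  merged <- list(runs[[1]])
  gap_len <- cfg$merge_gap_ms / (dt * 1000)
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1L < gap_len) merged[[length(merged)]] <- c(last[1], r[2])
    else merged[[length(merged) + 1L]] <- r
  }
  out <- do.call(rbind, lapply(merged, function(r) {
    data.frame(onset_idx = r[1], offset_idx = r[2],
               magnitude_deg = sqrt((x[r[2]] - x[r[1]])^2 + (y[r[2]] - y[r[1]])^2))
  }))
  out[out$magnitude_deg <= cfg$max_magnitude_deg, , drop = FALSE]
}

# fixational-like test trace: mean-reverting drift plus optional injected
# displacement pulses, both axes
drift_trace <- function(n, step_sd = 0.002, phi = 0.995) {
  list(x = as.numeric(stats::filter(rnorm(n, 0, step_sd), phi, method = "recursive")),
       y = as.numeric(stats::filter(rnorm(n, 0, step_sd), phi, method = "recursive")))
}

inject_pulse <- function(tr, at, magnitude, v_peak, theta = 0) {
  wf <- oculoeffort:::ms_waveform(magnitude, v_peak)
  span <- at:(at + wf$n_samples - 1L)
  tr$x[span] <- tr$x[span] + cos(theta) * wf$par - sin(theta) * wf$ort
  tr$y[span] <- tr$y[span] + sin(theta) * wf$par + cos(theta) * wf$ort
  n <- length(tr$x)
  if (at + wf$n_samples <= n) {
    tr$x[(at + wf$n_samples):n] <- tr$x[(at + wf$n_samples):n] + cos(theta) * magnitude
    tr$y[(at + wf$n_samples):n] <- tr$y[(at + wf$n_samples):n] + sin(theta) * magnitude
  }
  tr
}

match_rate <- function(truth, detected, tol_ms = 10) {
  if (!nrow(truth)) return(NA_real_)
  hits <- vapply(truth$onset_ms, function(o)
    nrow(detected) > 0 && any(abs(detected$onset_ms - o) <= tol_ms), logical(1))
  mean(hits)
}
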