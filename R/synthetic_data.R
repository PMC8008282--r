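# Synthetic-experiment generator.
#
# Emulates the 21-participant, 3-condition cue-acquisition experiment: a
# bimodal cue-count distribution per condition, fixational gaze built from
# mean-reverting drift plus microsaccades obeying a linear main sequence, and
# pupil traces whose per-epoch latent means scale with cue index with
# condition-specific slopes, on top of low-frequency hippus and effort-scaled
# high-frequency noise. Every injected event and latent epoch mean is kept in
# a ground-truth ledger so downstream detectors and models can be validated by
# parameter recovery.

#' Effect-structure parameters of the synthetic experiment
#'
#' Defaults encode the study conditions: cue-count probabilities per condition,
#' a microsaccade rate of 2 events/s at cue 1 declining by 0.355 events/s per
#' additional cue in the neutral condition (0.657 in aversive), a main sequence
#' with slope 376.37 1/s and intercept 12.91 deg/s, pupil dilation slopes of
#' 37.00 (neutral), 98.79 (aversive) and -28.86 (erotic) units per cue, and a
#' between-participant pupil baseline SD of 128.6 units.
#'
#' @param cue_count_probs 3 x 6 matrix (rows neutral/aversive/erotic) of
#'   probabilities over 1..6 acquired cues; each row sums to 1.
#' @param ms_rate_base microsaccade rate at cue 1 (events/s).
#' @param ms_rate_slope_per_cue named per-condition change in rate per
#'   additional cue (events/s); rates are floored at 0.05 events/s.
#' @param ms_magnitude_mean_deg median of the lognormal magnitude law (deg).
#' @param ms_magnitude_sd_deg log-scale SD of the magnitude law.
#' @param main_seq_slope,main_seq_intercept linear main sequence:
#'   peak velocity = slope * magnitude + intercept (1/s and deg/s).
#' @param main_seq_noise_sd SD of Gaussian velocity noise about the main
#'   sequence (deg/s); the default is calibrated so the detected-event
#'   main-sequence R^2 lands in [0.8, 0.9].
#' @param pupil_baseline_mean,pupil_baseline_sd_between participant pupil
#'   baseline distribution (arbitrary tracker units).
#' @param bcpd_slope_per_cue named per-condition evoked dilation per
#'   additional cue (units/cue).
#' @param hippus_amp,hippus_freq_hz low-frequency pupil oscillation.
#' @param pupil_hf_sd_base,pupil_hf_sd_per_cue high-frequency pupil noise SD
#'   at cue 1 and its increment per additional cue (units).
#' @param drift_sd_deg innovation SD of the mean-reverting fixational drift
#'   (deg per sample at 1 kHz).
#' @param eye_noise_sd_deg independent per-eye white measurement noise (deg).
#' @param blink_rate_per_s,blink_dur_ms blink Poisson process.
#' @param epoch_dur_ms_mean,epoch_dur_ms_sd lognormal self-paced epoch
#'   durations for cues >= 2 (ms).
#' @return An object of class `effect_params`.
#' @export
effect_params <- function(
    cue_count_probs = default_cue_probs(),
    ms_rate_base = 2.0,
    ms_rate_slope_per_cue = c(neutral = -0.355, aversive = -0.657, erotic = -0.355),
    ms_magnitude_mean_deg = 0.22,
    ms_magnitude_sd_deg = 0.35,
    main_seq_slope = 376.37,
    main_seq_intercept = 12.91,
    main_seq_noise_sd = 8,
    pupil_baseline_mean = 4000,
    pupil_baseline_sd_between = 128.6,
    bcpd_slope_per_cue = c(neutral = 37.00, aversive = 98.79, erotic = -28.86),
    hippus_amp = 30,
    hippus_freq_hz = 0.2,
    pupil_hf_sd_base = 50,
    pupil_hf_sd_per_cue = 10,
    drift_sd_deg = 0.0015,
    eye_noise_sd_deg = 0.005,
    blink_rate_per_s = 0.1,
    blink_dur_ms = 150,
    epoch_dur_ms_mean = 1500,
    epoch_dur_ms_sd = 500) {
  cue_count_probs <- as_cue_prob_matrix(cue_count_probs)
  ms_rate_slope_per_cue <- unlist(ms_rate_slope_per_cue)
  bcpd_slope_per_cue <- unlist(bcpd_slope_per_cue)
  if (any(abs(rowSums(cue_count_probs) - 1) > 1e-9))
    stop_oe("each cue_count_probs row must sum to 1", class = "oe_validation_error")
  if (main_seq_slope <= 0)
    stop_oe("main_seq_slope must be > 0", class = "oe_validation_error")
  for (nm in c("neutral", "aversive", "erotic")) {
    if (!nm %in% names(ms_rate_slope_per_cue) || !nm %in% names(bcpd_slope_per_cue))
      stop_oe("per-condition slopes must be named neutral/aversive/erotic",
              class = "oe_validation_error")
  }
  structure(list(
    cue_count_probs = cue_count_probs,
    ms_rate_base = ms_rate_base,
    ms_rate_slope_per_cue = ms_rate_slope_per_cue,
    ms_magnitude_mean_deg = ms_magnitude_mean_deg,
    ms_magnitude_sd_deg = ms_magnitude_sd_deg,
    main_seq_slope = main_seq_slope,
    main_seq_intercept = main_seq_intercept,
    main_seq_noise_sd = main_seq_noise_sd,
    pupil_baseline_mean = pupil_baseline_mean,
    pupil_baseline_sd_between = pupil_baseline_sd_between,
    bcpd_slope_per_cue = bcpd_slope_per_cue,
    hippus_amp = hippus_amp,
    hippus_freq_hz = hippus_freq_hz,
    pupil_hf_sd_base = pupil_hf_sd_base,
    pupil_hf_sd_per_cue = pupil_hf_sd_per_cue,
    drift_sd_deg = drift_sd_deg,
    eye_noise_sd_deg = eye_noise_sd_deg,
    blink_rate_per_s = blink_rate_per_s,
    blink_dur_ms = blink_dur_ms,
    epoch_dur_ms_mean = epoch_dur_ms_mean,
    epoch_dur_ms_sd = epoch_dur_ms_sd), class = "effect_params")
}

#' Per-condition cue-count probabilities of the decision task
#'
#' Rows neutral/aversive/erotic over 1..6 acquired cues; six-cue decisions
#' carry probability zero (they were too rare to tabulate).
#' @return A 3 x 6 matrix.
#' @export
default_cue_probs <- function() {
  m <- rbind(neutral  = c(0.41, 0.10, 0.06, 0.08, 0.35, 0.00),
             aversive = c(0.54, 0.12, 0.04, 0.01, 0.29, 0.00),
             erotic   = c(0.56, 0.10, 0.07, 0.02, 0.25, 0.00))
  colnames(m) <- as.character(1:6)
  m
}

#' Overall cue-count probabilities (all conditions pooled)
#' @return A probability vector over 1..6 cues.
#' @export
overall_cue_probs <- function() c(0.49, 0.11, 0.06, 0.04, 0.30, 0.00)

as_cue_prob_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(all(CONDITIONS %in% rownames(p)))
    return(p[CONDITIONS, , drop = FALSE])
  }
  # list form (e.g. from YAML): named list of numeric vectors
  do.call(rbind, lapply(stats::setNames(CONDITIONS, CONDITIONS),
                        function(cc) as.numeric(p[[cc]])))
}

#' Microsaccade rate for a cue index, with rate floor
#'
#' @param effects an `effect_params`.
#' @param condition condition label.
#' @param cue_index 1-based cue index.
#' @return Rate in events/s, floored at 0.05.
#' @export
ms_rate_for_cue <- function(effects, condition, cue_index) {
  pmax(0.05, effects$ms_rate_base +
         effects$ms_rate_slope_per_cue[[condition]] * (cue_index - 1))
}

#' Simulation configuration
#'
#' @param n_participants_per_condition named integer vector
#'   (neutral/aversive/erotic); defaults to the 8/7/6 design.
#' @param task a `task_spec`.
#' @param geometry a `screen_geometry`.
#' @param effects an `effect_params`.
#' @param seed integer; fully determines the generated dataset.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_participants_per_condition = c(neutral = 8L, aversive = 7L, erotic = 6L),
    task = task_spec(), geometry = default_geometry(),
    effects = effect_params(), seed = 1L) {
  npc <- n_participants_per_condition
  if (!all(CONDITIONS %in% names(npc)) || any(npc < 1))
    stop_oe("n_participants_per_condition must name all conditions with counts >= 1",
            class = "oe_validation_error")
  stopifnot(inherits(task, "task_spec"), inherits(geometry, "screen_geometry"),
            inherits(effects, "effect_params"))
  structure(list(n_participants_per_condition = npc[CONDITIONS],
                 task = task, geometry = geometry, effects = effects,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Sample per-trial cue counts
#'
#' @param n_trials number of draws.
#' @param probs probability vector over cue counts 1..length(probs).
#' @return Integer vector of cue counts.
#' @export
sample_cue_counts <- function(n_trials, probs) {
  if (abs(sum(probs) - 1) > 1e-9)
    stop_oe("cue-count probabilities must sum to 1", class = "oe_validation_error")
  if (any(probs < 0))
    stop_oe("cue-count probabilities must be non-negative", class = "oe_validation_error")
  if (n_trials == 0) return(integer(0))
  sample.int(length(probs), n_trials, replace = TRUE, prob = probs)
}

# ---------------------------------------------------------------------------
# Microsaccade waveform construction.
#
# The detector estimates velocity with the five-point digital filter
# v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt), whose output on a
# monotone displacement pulse of size A can never exceed A / (3 dt): the
# steep empirical main sequence therefore requires saccades with dynamic
# overshoot (net displacement smaller than the excursion), which is what real
# microsaccades show. Each injected event is a minimum-jerk main pulse to
# A * (1 + beta) followed by a minimum-jerk return of beta * A, and beta is
# solved per event so that the five-point-filtered peak velocity of the
# noise-free waveform equals the target main-sequence velocity exactly.

minjerk_ramp <- function(n) {
  s <- seq_len(n) / n
  10 * s^3 - 15 * s^4 + 6 * s^5
}

fivepoint_velocity <- function(x, dt) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 5) {
    idx <- 3:(n - 2)
    v[idx] <- (x[idx + 2] + x[idx + 1] - x[idx - 1] - x[idx - 2]) / (6 * dt)
  }
  v
}

# Displacement templates for a main phase of n1 samples and return of n2;
# memoised, they are pure functions of (n1, n2) at fixed dt.
.tpl_cache <- new.env(parent = emptyenv())

ms_templates <- function(n1, n2, dt) {
  key <- paste0(n1, "_", n2, "_", dt)
  hit <- get0(key, envir = .tpl_cache)
  if (!is.null(hit)) return(hit)
  pad <- 4L
  c0 <- c(rep(0, pad), minjerk_ramp(n1), rep(1, n2), rep(1, pad))
  c1 <- c(rep(0, pad), minjerk_ramp(n1), 1 - minjerk_ramp(n2), rep(0, pad))
  u0 <- fivepoint_velocity(c0, dt)
  u1 <- fivepoint_velocity(c1, dt)
  ok <- !is.na(u0)
  out <- list(c0 = c0, c1 = c1, u0 = u0[ok], u1 = u1[ok], pad = pad)
  assign(key, out, envir = .tpl_cache)
  out
}

# Solve the overshoot fraction so that max(u0 + beta * u1) = v_target / A.
solve_overshoot <- function(tpl, target_per_amp) {
  pos <- tpl$u1 > 1e-9
  if (!any(pos)) return(0)
  beta <- min((target_per_amp - tpl$u0[pos]) / tpl$u1[pos])
  max(beta, 0)
}

# Build the sampled displacement waveform for one event: `par` along the
# saccade axis, `ort` orthogonal to it. The parallel component is the
# overshooting pulse; the orthogonal component is a zero-net curvature bump
# spanning the velocity reversal, which keeps the elliptic detection
# criterion satisfied through the reversal (the filtered speed along the
# saccade axis necessarily dips to zero there) so the detector sees one
# contiguous event covering the full excursion and return. Returns the
# noise-free filtered peak speed the waveform encodes.
ms_waveform <- function(magnitude, v_target, dt = 1e-3) {
  # slow events (velocity below the line for their size) get a longer main
  # phase rather than a vanishing overshoot: real saccade duration grows as
  # peak velocity drops, and a longer pulse keeps the detected run above the
  # detector's minimum duration
  target_per_amp <- v_target / magnitude
  n1 <- 4L
  while (n1 < 12L) {
    if (max(ms_templates(n1, 4L, dt)$u0) <= target_per_amp - 10) break
    n1 <- n1 + 1L
  }
  v_ret <- 45                         # target return-phase peak velocity, deg/s
  n2 <- 4L
  for (it in 1:2) {
    tpl <- ms_templates(n1, n2, dt)
    beta <- solve_overshoot(tpl, v_target / magnitude)
    n2 <- max(4L, min(10L, as.integer(round(1.875 * beta * magnitude / (v_ret * dt)))))
  }
  tpl <- ms_templates(n1, n2, dt)
  beta <- solve_overshoot(tpl, v_target / magnitude)
  pad <- tpl$pad
  L <- 2L * pad + n1 + n2
  full_par <- magnitude * (tpl$c0 + beta * tpl$c1)
  vx <- fivepoint_velocity(full_par, dt)
  achieved <- magnitude * max(tpl$u0 + beta * tpl$u1)

  # curvature bump across the velocity reversal: the filtered speed along the
  # saccade axis passes through zero between excursion peak and return, so a
  # zero-net orthogonal excursion keeps the elliptic criterion satisfied there
  full_ort <- numeric(L)
  vxa <- abs(vx)
  supp <- which(!is.na(vx) & vxa >= 20)
  if (length(supp) >= 2) {
    hi <- max(supp[length(supp)], min(pad + n1 + n2 + 1L, L - 2L))
    gap <- setdiff(supp[1]:hi, supp)
    if (length(gap)) {
      g1 <- gap[1]
      rise <- g1:(g1 + 1L)
      fall <- (g1 + 2L):min(g1 + 5L, L)
      bump <- numeric(L)
      bump[rise] <- minjerk_ramp(2L)
      bump[fall] <- (1 - minjerk_ramp(4L))[seq_along(fall)]
      ub <- fivepoint_velocity(bump, dt)
      # orthogonal speed needed so the combined speed clears 14 deg/s
      # (about twice the detection threshold on clean recordings) at every
      # gap sample; the bump rise starts at the gap so its filtered
      # velocity there is substantial
      vy_req <- sqrt(pmax(14^2 - vxa[gap]^2, 0))
      gamma <- min(max(vy_req / pmax(abs(ub[gap]), 60)), 0.15)
      full_ort <- gamma * bump
    }
  }
  keep <- (pad + 1L):min(L, pad + n1 + n2 + 4L)
  list(par = full_par[keep], ort = full_ort[keep], n_samples = length(keep),
       overshoot = beta, peak_velocity = achieved)
}

# Truncated lognormal magnitude draw. The upper truncation keeps saccade
# excursions (magnitude times 1 + overshoot) inside the fixation dispersion
# window so events are not cut in half by the I-DT segmentation; the lower
# one keeps events above the detector noise floor.
draw_magnitudes <- function(n, effects) {
  out <- numeric(0)
  meanlog <- log(effects$ms_magnitude_mean_deg)
  while (length(out) < n) {
    cand <- stats::rlnorm(n - length(out), meanlog, effects$ms_magnitude_sd_deg)
    out <- c(out, cand[cand >= 0.12 & cand <= 0.42])
  }
  out
}

# Renewal event onsets with a refractory dead time, matching an expected
# stationary rate of `rate` events/s inside [0, dur_s).
draw_event_onsets <- function(dur_s, rate, refractory_s = 0.06) {
  if (rate <= 0) return(numeric(0))
  exp_mean <- max(1 / rate - refractory_s, 1e-3)
  onsets <- numeric(0)
  t <- stats::rexp(1, 1 / exp_mean)
  while (t < dur_s) {
    onsets <- c(onsets, t)
    t <- t + refractory_s + stats::rexp(1, 1 / exp_mean)
  }
  onsets
}

#' Simulate one trial of the cue-acquisition task
#'
#' Lays out cue epochs (the first cue with its fixed presentation duration,
#' later self-paced epochs drawn from a lognormal), synthesises a cyclopean
#' fixational trace (mean-reverting drift plus injected microsaccades on the
#' main sequence), a pupil trace (participant baseline, condition-specific
#' evoked dilation per cue, hippus, effort-scaled high-frequency noise),
#' inserts blinks as missing runs, and emits both eyes as the common signal
#' plus independent per-eye noise.
#'
#' @param participant_id,trial_id identifiers for the emitted records.
#' @param condition condition label.
#' @param n_cues number of acquired cues (1..6).
#' @param cfg a `simulation_config`.
#' @param baseline participant pupil baseline (arbitrary units).
#' @param is_training if TRUE the trial has one cue epoch and no evoked
#'   dilation or noise scaling beyond cue 1 (training trials define the
#'   baseline).
#' @return List with elements `recording` (a `gaze_recording`), `trial` (a
#'   one-row trial table) and `truth` (ground-truth ledger for the trial:
#'   injected events and per-epoch latent means and rates).
#' @export
simulate_trial <- function(participant_id, trial_id, condition, n_cues, cfg,
                           baseline, is_training = FALSE) {
  if (n_cues < 1 || n_cues > cfg$task$n_cues_max)
    stop_oe("n_cues out of range", class = "oe_validation_error")
  if (is.null(cfg$geometry$screen_width_cm))
    stop_oe("geometry lacks physical screen size", class = "oe_config_error")
  eff <- cfg$effects
  dt <- 1e-3

  # --- epoch layout -------------------------------------------------------
  durs <- cfg$task$first_cue_ms
  if (n_cues > 1) {
    m <- eff$epoch_dur_ms_mean; s <- eff$epoch_dur_ms_sd
    sdlog <- sqrt(log(1 + (s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    durs <- c(durs, pmax(300, round(stats::rlnorm(n_cues - 1, meanlog, sdlog))))
  }
  offsets <- cumsum(durs)
  onsets <- c(0, offsets[-n_cues])
  tail_ms <- 150L   # response interval after the last cue; lets events near
                    # the final epoch boundary complete inside the recording
  n <- as.integer(offsets[n_cues]) + tail_ms
  t <- seq_len(n) - 1

  # --- fixational drift (mean-reverting random walk, per axis) ------------
  phi <- 0.995
  x <- as.numeric(stats::filter(stats::rnorm(n, 0, eff$drift_sd_deg), phi,
                                method = "recursive"))
  y <- as.numeric(stats::filter(stats::rnorm(n, 0, eff$drift_sd_deg), phi,
                                method = "recursive"))

  # --- blinks (drawn first: no microsaccades are injected during a blink) --
  n_blinks <- stats::rpois(1, eff$blink_rate_per_s * n / 1000)
  blink_mask <- rep(FALSE, n)
  if (n_blinks > 0) {
    b_on <- sort(stats::runif(n_blinks, 0, max(n - eff$blink_dur_ms - 1, 1)))
    for (b in b_on) {
      span <- (as.integer(b) + 1L):min(n, as.integer(b) + eff$blink_dur_ms)
      blink_mask[span] <- TRUE
    }
  }
  blink_guard <- 120L  # keep events clear of the masked-and-padded window
  event_excluded <- rep(FALSE, n)
  if (any(blink_mask)) {
    br <- true_runs(blink_mask)
    for (i in seq_len(nrow(br)))
      event_excluded[max(1, br[i, "start"] - blink_guard):
                       min(n, br[i, "end"] + blink_guard)] <- TRUE
  }

  # --- microsaccades ------------------------------------------------------
  # Events re-center gaze (square-wave-like alternation, as in real
  # fixational data) and their direction — in rare cases their size — is
  # chosen so the running position range of the current inter-blink segment
  # stays inside the I-DT dispersion window: fixational eye movements are by
  # definition movements that do not leave fixation.
  seg_id <- cumsum(c(TRUE, diff(blink_mask) != 0))
  seg_ext <- new.env(parent = emptyenv())
  range_budget <- 0.88
  events <- list()
  for (k in seq_len(n_cues)) {
    cue_idx <- if (is_training) 1L else k
    rate <- ms_rate_for_cue(eff, condition, cue_idx)
    # events are drawn on blink-free (visible) time at compensated
    # intensity so the realised rate per second of epoch matches `rate`
    ep_idx <- (onsets[k] + 1L):min(onsets[k] + durs[k], n)
    vis_idx <- ep_idx[!event_excluded[ep_idx]]
    dur_s <- durs[k] / 1000
    vis_s <- length(vis_idx) / 1000
    if (vis_s < 0.1) next
    ons <- draw_event_onsets(vis_s, rate * dur_s / vis_s)
    for (o in ons) {
      A <- draw_magnitudes(1, eff)
      v_noise <- stats::rnorm(1, 0, eff$main_seq_noise_sd)
      i0 <- vis_idx[round(o * 1000) + 1L]
      if (is.na(i0) || i0 + 35L > n) next
      px <- x[i0]; py <- y[i0]
      key <- as.character(seg_id[i0])
      ext <- get0(key, envir = seg_ext,
                  ifnotfound = c(px, px, py, py))  # xmin xmax ymin ymax
      for (attempt in 1:11) {
        if (attempt == 6) A <- 0.8 * A
        if (attempt == 10) A <- 0.8 * A
        v <- max(eff$main_seq_slope * A + eff$main_seq_intercept + v_noise,
                 165 * A + 2)         # keep the waveform solvable
        wf <- ms_waveform(A, v, dt)
        # last attempt: place along the exact re-centering direction rather
        # than reject (rejection would thin the event rate)
        jitter <- if (attempt <= 4) 0.25 else if (attempt <= 10) 1.5 else 0
        theta <- if (sqrt(px^2 + py^2) > 0.1 || attempt == 11)
          atan2(-py, -px) + stats::rnorm(1, 0, jitter)
        else stats::runif(1, 0, 2 * pi)
        sgn <- sample(c(-1, 1), 1)    # curvature handedness
        ux <- cos(theta); uy <- sin(theta)
        reach <- (1 + wf$overshoot) * A
        gam <- max(wf$ort)
        cand_x <- c(px, px + reach * ux, px + A * ux,
                    px + 0.5 * reach * ux - sgn * gam * uy)
        cand_y <- c(py, py + reach * uy, py + A * uy,
                    py + 0.5 * reach * uy + sgn * gam * ux)
        new_ext <- c(min(ext[1], cand_x), max(ext[2], cand_x),
                     min(ext[3], cand_y), max(ext[4], cand_y))
        if (attempt == 11 ||
            (new_ext[2] - new_ext[1]) + (new_ext[4] - new_ext[3]) <= range_budget)
          break
      }
      assign(key, new_ext, envir = seg_ext)
      span <- i0:(i0 + wf$n_samples - 1L)
      x[span] <- x[span] + ux * wf$par - sgn * uy * wf$ort
      y[span] <- y[span] + uy * wf$par + sgn * ux * wf$ort
      if (i0 + wf$n_samples <= n) {   # displacement persists after the event
        x[(i0 + wf$n_samples):n] <- x[(i0 + wf$n_samples):n] + ux * A
        y[(i0 + wf$n_samples):n] <- y[(i0 + wf$n_samples):n] + uy * A
      }
      events[[length(events) + 1L]] <- data.frame(
        epoch_index = k, onset_ms = t[i0],
        offset_ms = t[i0] + wf$n_samples - 1,
        magnitude_deg = A, peak_velocity_dps = wf$peak_velocity,
        overshoot = wf$overshoot)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(epoch_index = integer(), onset_ms = numeric(), offset_ms = numeric(),
               magnitude_deg = numeric(), peak_velocity_dps = numeric(),
               overshoot = numeric())

  # --- pupil --------------------------------------------------------------
  cue_of_sample <- c(rep(seq_len(n_cues), durs), rep(n_cues, tail_ms))
  evoked_cue <- if (is_training) rep(1L, n) else cue_of_sample
  latent <- baseline + eff$bcpd_slope_per_cue[[condition]] * (evoked_cue - 1)
  hip_phase <- stats::runif(1, 0, 2 * pi)
  hippus <- eff$hippus_amp * sin(2 * pi * eff$hippus_freq_hz * t / 1000 + hip_phase)
  hf_sd <- eff$pupil_hf_sd_base + eff$pupil_hf_sd_per_cue * (evoked_cue - 1)
  pupil <- latent + hippus + stats::rnorm(n, 0, hf_sd)

  # --- per-eye emission in pixels -----------------------------------------
  geom <- cfg$geometry
  xl <- degrees_to_pixels(x + stats::rnorm(n, 0, eff$eye_noise_sd_deg), geom, "x")
  xr <- degrees_to_pixels(x + stats::rnorm(n, 0, eff$eye_noise_sd_deg), geom, "x")
  yl <- degrees_to_pixels(y + stats::rnorm(n, 0, eff$eye_noise_sd_deg), geom, "y")
  yr <- degrees_to_pixels(y + stats::rnorm(n, 0, eff$eye_noise_sd_deg), geom, "y")
  pl <- pupil + stats::rnorm(n, 0, 2)
  pr <- pupil + stats::rnorm(n, 0, 2)
  for (ch in c("xl", "xr", "yl", "yr", "pl", "pr"))
    assign(ch, replace(get(ch), blink_mask, NA_real_))

  # --- behavioral outcome (cosmetic: Bernoulli at best-cue validity) ------
  choice <- sample(c("A", "B"), 1)
  accuracy <- stats::rbinom(1, 1, cfg$task$cue_validities[1])

  rec <- gaze_recording(participant_id, trial_id, t, xl, yl, xr, yr, pl, pr)
  tr <- trial_record(participant_id, condition, trial_id, is_training,
                     onsets, offsets, choice, accuracy)
  truth <- list(
    events = events,
    epochs = data.frame(
      epoch_index = seq_len(n_cues), onset_ms = onsets, offset_ms = offsets,
      latent_pupil_mean = baseline +
        eff$bcpd_slope_per_cue[[condition]] *
        (if (is_training) rep(0, n_cues) else seq_len(n_cues) - 1),
      ms_rate = ms_rate_for_cue(eff, condition,
                                if (is_training) rep(1L, n_cues) else seq_len(n_cues))),
    baseline = baseline)
  list(recording = rec, trial = tr, truth = truth)
}

#' Generate a complete synthetic experiment dataset
#'
#' Per participant: `n_training` training trials (one cue epoch, no evoked
#' dilation — these define the pupil baseline) followed by `n_trials` main
#' trials with cue counts drawn from the condition's cue-count distribution.
#' The same seed always yields an identical dataset.
#'
#' @param cfg a `simulation_config`.
#' @return An `experiment_dataset` whose `truth` element holds the
#'   ground-truth ledger (participant baselines, injected events, latent
#'   per-epoch means and rates).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  eff <- cfg$effects
  recs <- list()
  trials <- list()
  truth_events <- list()
  truth_epochs <- list()
  parts <- list()
  pid <- 0L
  for (cond in CONDITIONS) {
    for (i in seq_len(cfg$n_participants_per_condition[[cond]])) {
      pid <- pid + 1L
      p <- sprintf("P%02d", pid)
      baseline <- stats::rnorm(1, eff$pupil_baseline_mean, eff$pupil_baseline_sd_between)
      parts[[p]] <- data.frame(participant = p, condition = cond,
                               baseline = baseline)
      n_tr <- cfg$task$n_training
      cues_main <- sample_cue_counts(cfg$task$n_trials,
                                     eff$cue_count_probs[cond, ])
      for (j in seq_len(n_tr + cfg$task$n_trials)) {
        training <- j <= n_tr
        ncue <- if (training) 1L else cues_main[j - n_tr]
        sim <- simulate_trial(p, j, cond, ncue, cfg, baseline, training)
        recs[[key_pt(p, j)]] <- sim$recording
        trials[[length(trials) + 1L]] <- sim$trial
        if (nrow(sim$truth$events)) {
          ev <- sim$truth$events; ev$participant <- p; ev$trial <- j
          truth_events[[length(truth_events) + 1L]] <- ev
        }
        ep <- sim$truth$epochs; ep$participant <- p; ep$trial <- j
        ep$is_training <- training
        truth_epochs[[length(truth_epochs) + 1L]] <- ep
      }
    }
  }
  truth <- list(
    participants = do.call(rbind, parts),
    events = if (length(truth_events)) do.call(rbind, truth_events) else NULL,
    epochs = do.call(rbind, truth_epochs))
  rownames(truth$participants) <- NULL
  experiment_dataset(cfg$geometry, cfg$task, recs, do.call(rbind, trials), truth)
}
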