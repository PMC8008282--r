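# Velocity-threshold microsaccade detection within fixations, main-sequence
# regression and per-epoch event summaries.
#
# Detection follows the classic velocity-threshold scheme: a five-point
# digital derivative, a median-based noise estimate per axis, and an elliptic
# criterion (vx/eta_x)^2 + (vy/eta_y)^2 > 1 with eta = lambda * sigma.
# Detection runs on the cyclopean (averaged-eye) signal; magnitude is the
# start-to-end displacement of the detected event (not the peak-to-peak
# excursion — conventions vary in the literature, this one is pinned here).

#' Microsaccade detector parameters
#'
#' @param lambda_mult threshold multiplier lambda (unitless, default 6).
#' @param velocity_window samples in the velocity estimator (odd, default 5;
#'   only the five-point estimator is implemented).
#' @param min_dur_ms minimal event duration (ms, >= 3).
#' @param merge_gap_ms events closer than this merge into one (ms).
#' @param max_magnitude_deg events larger than this are discarded (deg);
#'   beyond ~1 degree a saccade is no longer "micro".
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(lambda_mult = 6, velocity_window = 5L,
                            min_dur_ms = 6, merge_gap_ms = 20,
                            max_magnitude_deg = 1.0) {
  if (lambda_mult <= 0)
    stop_oe("lambda_mult must be > 0", class = "oe_validation_error")
  if (velocity_window < 5L || velocity_window %% 2L == 0L)
    stop_oe("velocity_window must be odd and >= 5", class = "oe_validation_error")
  if (min_dur_ms < 3)
    stop_oe("min_dur_ms must be >= 3", class = "oe_validation_error")
  structure(list(lambda_mult = lambda_mult,
                 velocity_window = as.integer(velocity_window),
                 min_dur_ms = min_dur_ms, merge_gap_ms = merge_gap_ms,
                 max_magnitude_deg = max_magnitude_deg),
            class = "detector_config")
}

#' Five-point velocity estimate
#'
#' `v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)` per axis; the
#' first and last two samples are undefined (NA), as is any sample whose
#' window touches missing data. Exact on linear motion.
#'
#' @param x,y position series in degrees.
#' @param dt sampling interval in seconds.
#' @param window estimator window (must be 5).
#' @return List with `vx`, `vy` in deg/s (same length as input).
#' @export
compute_velocity <- function(x, y, dt = 1e-3, window = 5L) {
  if (window != 5L)
    stop_oe("only the five-point velocity estimator is implemented", class = "oe_validation_error")
  if (length(x) < window)
    return(list(vx = rep(NA_real_, length(x)), vy = rep(NA_real_, length(x))))
  list(vx = fivepoint_velocity(x, dt), vy = fivepoint_velocity(y, dt))
}

#' Median-based velocity noise estimate and elliptic thresholds
#'
#' `sigma_a^2 = median(v_a^2) - median(v_a)^2` per axis (a robust spread
#' estimate insensitive to the saccadic tails), floored at a small epsilon;
#' `eta_a = lambda * sigma_a`.
#'
#' @param vx,vy velocity series (deg/s); NAs ignored.
#' @param lambda threshold multiplier.
#' @return Named numeric vector `c(eta_x, eta_y)` with attribute `sigma`.
#' @export
estimate_thresholds <- function(vx, vy, lambda = 6) {
  vx <- vx[!is.na(vx)]; vy <- vy[!is.na(vy)]
  if (length(vx) < 10 || length(vy) < 10)
    stop_oe("need at least 10 defined velocity samples to estimate thresholds",
            class = "oe_insufficient_data")
  sig <- function(v) sqrt(max(stats::median(v^2) - stats::median(v)^2, 1e-12))
  s <- c(sig(vx), sig(vy))
  structure(c(eta_x = lambda * s[1], eta_y = lambda * s[2]), sigma = s)
}

#' Detect microsaccades in one fixation slice
#'
#' Candidate samples satisfy the elliptic criterion
#' `(vx/eta_x)^2 + (vy/eta_y)^2 > 1`; maximal candidate runs lasting at least
#' `min_dur_ms` become events; events separated by less than `merge_gap_ms`
#' are merged; events whose start-to-end displacement exceeds
#' `max_magnitude_deg` are discarded.
#'
#' @param x,y position slice in degrees (one fixation; no missing samples).
#' @param dt sampling interval in seconds.
#' @param cfg a `detector_config`.
#' @param thresholds optional `c(eta_x, eta_y)`; estimated from the slice
#'   when omitted.
#' @param t_ms optional timestamps; defaults to 0-based ms at `dt`.
#' @return data.frame with `onset_ms`, `offset_ms`, `onset_idx`, `offset_idx`,
#'   `magnitude_deg`, `peak_velocity_dps`.
#' @export
detect_microsaccades <- function(x, y, dt = 1e-3, cfg = detector_config(),
                                 thresholds = NULL, t_ms = NULL) {
  empty <- data.frame(onset_ms = numeric(), offset_ms = numeric(),
                      onset_idx = integer(), offset_idx = integer(),
                      magnitude_deg = numeric(), peak_velocity_dps = numeric())
  n <- length(x)
  if (is.null(t_ms)) t_ms <- (seq_len(n) - 1) * dt * 1000
  v <- compute_velocity(x, y, dt, cfg$velocity_window)
  if (all(is.na(v$vx))) return(empty)
  if (is.null(thresholds)) thresholds <- estimate_thresholds(v$vx, v$vy, cfg$lambda_mult)
  crit <- (v$vx / thresholds[["eta_x"]])^2 + (v$vy / thresholds[["eta_y"]])^2 > 1
  runs <- true_runs(crit)
  if (nrow(runs) == 0) return(empty)
  min_len <- ceiling(cfg$min_dur_ms / (dt * 1000))
  runs <- runs[(runs[, "end"] - runs[, "start"] + 1L) >= min_len, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  # merge events separated by less than merge_gap_ms
  gap_len <- cfg$merge_gap_ms / (dt * 1000)
  merged <- list(runs[1, ])
  for (i in seq_len(nrow(runs))[-1]) {
    last <- merged[[length(merged)]]
    if (runs[i, "start"] - last["end"] - 1L < gap_len) {
      last["end"] <- runs[i, "end"]
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- runs[i, ]
    }
  }
  speed <- sqrt(v$vx^2 + v$vy^2)
  out <- lapply(merged, function(r) {
    a <- r[["start"]]; b <- r[["end"]]
    data.frame(onset_ms = t_ms[a], offset_ms = t_ms[b],
               onset_idx = a, offset_idx = b,
               magnitude_deg = sqrt((x[b] - x[a])^2 + (y[b] - y[a])^2),
               peak_velocity_dps = max(speed[a:b], na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  out <- out[out$magnitude_deg <= cfg$max_magnitude_deg, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect microsaccades across all fixations of a preprocessed recording
#'
#' Velocities are computed on the full cyclopean trace and thresholds are
#' estimated per fixation when it offers at least 50 defined velocity samples,
#' otherwise from all fixation samples of the trial pooled.
#'
#' @param pre output of [preprocess_recording()].
#' @param cfg a `detector_config`.
#' @return data.frame of events with `fixation_id` and absolute `onset_ms` /
#'   `offset_ms` plus trial-level indices.
#' @export
detect_trial_microsaccades <- function(pre, cfg = detector_config()) {
  empty <- data.frame(onset_ms = numeric(), offset_ms = numeric(),
                      onset_idx = integer(), offset_idx = integer(),
                      magnitude_deg = numeric(), peak_velocity_dps = numeric(),
                      fixation_id = integer())
  fx <- pre$fixations
  if (nrow(fx) == 0) return(empty)
  dt <- pre$dt_ms / 1000
  v <- compute_velocity(pre$x_deg, pre$y_deg, dt)
  pooled_idx <- unlist(lapply(seq_len(nrow(fx)), function(i)
    fx$start_idx[i]:fx$end_idx[i]))
  pooled <- tryCatch(
    estimate_thresholds(v$vx[pooled_idx], v$vy[pooled_idx], cfg$lambda_mult),
    oe_insufficient_data = function(e) NULL)
  res <- list()
  for (i in seq_len(nrow(fx))) {
    idx <- fx$start_idx[i]:fx$end_idx[i]
    vx <- v$vx[idx]; vy <- v$vy[idx]
    thr <- if (sum(!is.na(vx)) >= 50) {
      estimate_thresholds(vx, vy, cfg$lambda_mult)
    } else pooled
    if (is.null(thr)) next
    ev <- detect_microsaccades(pre$x_deg[idx], pre$y_deg[idx], dt, cfg,
                               thresholds = thr, t_ms = pre$t[idx])
    if (nrow(ev)) {
      ev$onset_idx <- ev$onset_idx + fx$start_idx[i] - 1L
      ev$offset_idx <- ev$offset_idx + fx$start_idx[i] - 1L
      ev$fixation_id <- i
      res[[length(res) + 1L]] <- ev
    }
  }
  if (length(res)) do.call(rbind, res) else empty
}

#' Main-sequence regression of peak velocity on magnitude
#'
#' Ordinary least squares of event peak velocity on event magnitude — the
#' standard validity check that detected events behave like saccades.
#'
#' @param events data.frame with `magnitude_deg` and `peak_velocity_dps`
#'   (rows with NA in either are dropped).
#' @return An object of class `main_sequence_fit` with `slope` (1/s),
#'   `intercept` (deg/s), `r_squared`, `n_events`, `slope_se`, `intercept_se`.
#' @export
fit_main_sequence <- function(events) {
  m <- events$magnitude_deg
  v <- events$peak_velocity_dps
  ok <- !is.na(m) & !is.na(v)
  m <- m[ok]; v <- v[ok]
  if (length(m) < 2)
    stop_oe("need at least 2 events to fit the main sequence", class = "oe_insufficient_data")
  if (stats::sd(m) == 0)
    stop_oe("all magnitudes equal: degenerate design", class = "oe_degenerate_design")
  fit <- stats::lm(v ~ m)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n_events = length(m),
                 slope_se = sm$coefficients[2, 2],
                 intercept_se = sm$coefficients[1, 2],
                 f_statistic = unname(sm$fstatistic[1]),
                 model = fit),
            class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf("Main sequence: peak velocity = %.2f * magnitude + %.2f\n",
              x$slope, x$intercept))
  cat(sprintf("  n = %d events, R^2 = %.3f, slope SE = %.3f\n",
              x$n_events, x$r_squared, x$slope_se))
  invisible(x)
}

#' @export
coef.main_sequence_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.main_sequence_fit <- function(object, ...) summary(object$model, ...)

#' Per-epoch microsaccade rate and magnitude
#'
#' @param events event data.frame (onset-based assignment: an event belongs
#'   to the epoch its onset falls in).
#' @param epochs data.frame with `epoch_index`, `onset_ms`, `offset_ms`.
#' @return data.frame with `epoch_index`, `n_events`, `ms_rate` (events/s)
#'   and `ms_magnitude` (mean magnitude, NA when no events).
#' @export
epoch_summaries <- function(events, epochs) {
  if (any(epochs$offset_ms <= epochs$onset_ms))
    stop_oe("zero or negative epoch duration", class = "oe_validation_error")
  res <- lapply(seq_len(nrow(epochs)), function(i) {
    sel <- events$onset_ms >= epochs$onset_ms[i] & events$onset_ms < epochs$offset_ms[i]
    dur_s <- (epochs$offset_ms[i] - epochs$onset_ms[i]) / 1000
    data.frame(epoch_index = epochs$epoch_index[i],
               n_events = sum(sel),
               ms_rate = sum(sel) / dur_s,
               ms_magnitude = if (any(sel)) mean(events$magnitude_deg[sel]) else NA_real_)
  })
  do.call(rbind, res)
}
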