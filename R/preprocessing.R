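# Stages between raw binocular samples and event/metric extraction: blink
# detection and masking, binocular averaging, pixel-to-degree conversion,
# pupil smoothing and dispersion-based fixation segmentation.

#' Preprocessing parameters
#'
#' @param blink_pad_ms symmetric padding around missing-pupil runs (ms);
#'   100 ms covers the lid-closure pupil artifact around a blink.
#' @param pupil_smooth_window_ms centered moving-average window (ms).
#' @param fixation_dispersion_deg I-DT dispersion ceiling (max - min summed
#'   over both axes, degrees).
#' @param fixation_min_dur_ms minimum fixation duration (ms).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(blink_pad_ms = 100, pupil_smooth_window_ms = 100,
                              fixation_dispersion_deg = 1.0,
                              fixation_min_dur_ms = 100) {
  for (nm in names(formals(preprocess_config)))
    assert_scalar_num(get(nm), nm, positive = TRUE)
  structure(list(blink_pad_ms = blink_pad_ms,
                 pupil_smooth_window_ms = pupil_smooth_window_ms,
                 fixation_dispersion_deg = fixation_dispersion_deg,
                 fixation_min_dur_ms = fixation_min_dur_ms),
            class = "preprocess_config")
}

#' Detect blinks as padded runs of missing pupil
#'
#' Maximal runs where either eye's pupil is missing become intervals, extended
#' by `pad_ms` on each side; overlapping or touching intervals are merged.
#'
#' @param rec a `gaze_recording`.
#' @param pad_ms symmetric padding in ms.
#' @return data.frame with `onset_ms`, `offset_ms`, `eye` (left/right/both).
#' @export
detect_blinks <- function(rec, pad_ms = 100) {
  na_l <- is.na(rec$pl)
  na_r <- is.na(rec$pr)
  runs <- true_runs(na_l | na_r)
  if (nrow(runs) == 0)
    return(data.frame(onset_ms = numeric(), offset_ms = numeric(), eye = character(),
                      stringsAsFactors = FALSE))
  iv <- data.frame(
    onset_ms = rec$t[runs[, "start"]] - pad_ms,
    offset_ms = rec$t[runs[, "end"]] + pad_ms,
    eye = vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs[i, "start"]:runs[i, "end"]
      l <- any(na_l[idx]); r <- any(na_r[idx])
      if (l && r) "both" else if (l) "left" else "right"
    }, character(1)),
    stringsAsFactors = FALSE)
  # merge overlapping/touching intervals
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv$onset_ms[i] <= merged$offset_ms[last]) {
      merged$offset_ms[last] <- max(merged$offset_ms[last], iv$offset_ms[i])
      if (merged$eye[last] != iv$eye[i]) merged$eye[last] <- "both"
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Mask blink intervals in a recording
#'
#' Sets all channels to missing inside each blink interval; the sample count
#' is unchanged. Applying the mask twice equals applying it once.
#'
#' @param rec a `gaze_recording`.
#' @param blinks data.frame from [detect_blinks()].
#' @return A masked `gaze_recording`.
#' @export
mask_blinks <- function(rec, blinks) {
  if (nrow(blinks) == 0) return(rec)
  bad <- rep(FALSE, length(rec$t))
  for (i in seq_len(nrow(blinks)))
    bad <- bad | (rec$t >= blinks$onset_ms[i] & rec$t <= blinks$offset_ms[i])
  for (ch in c("xl", "yl", "xr", "yr", "pl", "pr"))
    rec[[ch]][bad] <- NA_real_
  rec
}

#' Average the two eyes into a cyclopean series
#'
#' Per-sample arithmetic mean of left and right channels; when exactly one eye
#' is missing the present eye is used; both missing gives missing. Pupil is
#' averaged identically.
#'
#' @param rec a `gaze_recording`.
#' @return data.frame with `t`, `x`, `y`, `p` (pixels / arbitrary units).
#' @export
average_eyes <- function(rec) {
  avg2 <- function(a, b) {
    out <- rowMeans(cbind(a, b), na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
  data.frame(t = rec$t,
             x = avg2(rec$xl, rec$xr),
             y = avg2(rec$yl, rec$yr),
             p = avg2(rec$pl, rec$pr))
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' Degrees are taken about the screen center, per axis:
#' `deg = atan2(offset_cm, distance_cm) * 180 / pi`.
#'
#' @param px pixel coordinates.
#' @param geometry a `screen_geometry`.
#' @param axis `"x"` or `"y"`.
#' @return Degrees relative to screen center (y grows downward).
#' @export
pixels_to_degrees <- function(px, geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (geometry$distance_cm <= 0)
    stop_oe("viewing distance must be > 0", class = "oe_config_error")
  if (axis == "x") {
    off_cm <- (px - geometry$screen_width_px / 2) *
      geometry$screen_width_cm / geometry$screen_width_px
  } else {
    off_cm <- (px - geometry$screen_height_px / 2) *
      geometry$screen_height_cm / geometry$screen_height_px
  }
  atan2(off_cm, geometry$distance_cm) * 180 / pi
}

#' Convert degrees about screen center back to pixel coordinates
#'
#' Inverse of [pixels_to_degrees()].
#' @param deg degrees relative to screen center.
#' @param geometry a `screen_geometry`.
#' @param axis `"x"` or `"y"`.
#' @return Pixel coordinates.
#' @export
degrees_to_pixels <- function(deg, geometry, axis = c("x", "y")) {
  axis <- match.arg(axis)
  off_cm <- tan(deg * pi / 180) * geometry$distance_cm
  if (axis == "x") {
    off_cm * geometry$screen_width_px / geometry$screen_width_cm +
      geometry$screen_width_px / 2
  } else {
    off_cm * geometry$screen_height_px / geometry$screen_height_cm +
      geometry$screen_height_px / 2
  }
}

#' Smooth a pupil series with a centered moving average
#'
#' Missing samples are ignored inside the window; output is missing only where
#' the whole window is missing. Length is preserved; partial windows at the
#' edges average over the available samples.
#'
#' @param p pupil series.
#' @param window_ms window length in ms.
#' @param dt_ms sampling interval in ms.
#' @return Smoothed series of the same length.
#' @export
smooth_pupil <- function(p, window_ms = 100, dt_ms = 1) {
  w <- max(3L, as.integer(round(window_ms / dt_ms)))
  if (w %% 2L == 0L) w <- w + 1L
  moving_average_na(p, w)
}

#' Dispersion-threshold (I-DT) fixation detection
#'
#' Greedy I-DT segmentation: starting from the earliest admissible sample, the
#' window of minimum duration is slid until its dispersion (max - min summed
#' over the two axes) is at or below the ceiling, then grown until the
#' dispersion would exceed it; the grown window is one fixation and the scan
#' resumes after it. Missing samples (blink gaps) terminate fixations.
#'
#' @param t timestamps (ms).
#' @param x,y gaze in degrees.
#' @param cfg a `preprocess_config`.
#' @param dt_ms sampling interval (ms).
#' @return data.frame with `onset_ms`, `offset_ms`, `x`, `y` (centroid),
#'   `dispersion`, `start_idx`, `end_idx`.
#' @export
detect_fixations <- function(t, x, y, cfg = preprocess_config(), dt_ms = 1) {
  w <- max(2L, as.integer(round(cfg$fixation_min_dur_ms / dt_ms)))
  theta <- cfg$fixation_dispersion_deg
  valid <- !is.na(x) & !is.na(y)
  segs <- true_runs(valid)
  fix <- list()
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, "start"]; b <- segs[s, "end"]
    m <- b - a + 1L
    if (m < w) next
    xs <- x[a:b]; ys <- y[a:b]
    # dispersion of every minimum-duration window in this segment; computed
    # lazily — most segments never slide the start window
    win_disp <- NULL
    roll_range <- function(z) {
      k <- length(z) - w + 1L
      shifted <- lapply(seq_len(w), function(j) z[j:(j + k - 1L)])
      do.call(pmax, shifted) - do.call(pmin, shifted)
    }
    i <- 1L
    n_win <- m - w + 1L
    while (i <= n_win) {
      wi <- i:(i + w - 1L)
      if ((max(xs[wi]) - min(xs[wi])) + (max(ys[wi]) - min(ys[wi])) > theta) {
        if (is.null(win_disp)) win_disp <- roll_range(xs) + roll_range(ys)
        nxt <- which(win_disp[i:n_win] <= theta)
        if (!length(nxt)) break
        i <- i + nxt[1] - 1L
      }
      # grow the window from i until dispersion exceeds theta
      cx_max <- cummax(xs[i:m]); cx_min <- cummin(xs[i:m])
      cy_max <- cummax(ys[i:m]); cy_min <- cummin(ys[i:m])
      disp <- (cx_max - cx_min) + (cy_max - cy_min)
      over <- which(disp > theta)
      e <- if (length(over)) i + over[1] - 2L else m
      idx <- (a + i - 1L):(a + e - 1L)
      fix[[length(fix) + 1L]] <- data.frame(
        onset_ms = t[idx[1]], offset_ms = t[idx[length(idx)]],
        x = mean(x[idx]), y = mean(y[idx]),
        dispersion = (max(x[idx]) - min(x[idx])) + (max(y[idx]) - min(y[idx])),
        start_idx = idx[1], end_idx = idx[length(idx)])
      i <- e + 1L
    }
  }
  if (length(fix)) {
    out <- do.call(rbind, fix)
    rownames(out) <- NULL
    out
  } else {
    data.frame(onset_ms = numeric(), offset_ms = numeric(), x = numeric(),
               y = numeric(), dispersion = numeric(), start_idx = integer(),
               end_idx = integer())
  }
}

#' Run all preprocessing stages on one recording
#'
#' Blink detection and masking, binocular averaging, conversion to degrees,
#' pupil smoothing and fixation segmentation.
#'
#' @param rec a `gaze_recording`.
#' @param geometry a `screen_geometry`.
#' @param cfg a `preprocess_config`.
#' @param fixations set FALSE to skip fixation segmentation (pupil-only use).
#' @return List with `t`, `x_deg`, `y_deg`, `pupil` (cyclopean, blink-masked),
#'   `pupil_smooth`, `blinks`, `fixations`, `dt_ms`.
#' @export
preprocess_recording <- function(rec, geometry, cfg = preprocess_config(),
                                 fixations = TRUE) {
  blinks <- detect_blinks(rec, cfg$blink_pad_ms)
  masked <- mask_blinks(rec, blinks)
  cyc <- average_eyes(masked)
  dt_ms <- if (length(rec$t) > 1) stats::median(diff(rec$t)) else 1
  x_deg <- pixels_to_degrees(cyc$x, geometry, "x")
  y_deg <- pixels_to_degrees(cyc$y, geometry, "y")
  fixes <- if (fixations) detect_fixations(cyc$t, x_deg, y_deg, cfg, dt_ms)
  else detect_fixations(numeric(0), numeric(0), numeric(0), cfg, dt_ms)
  list(t = cyc$t, x_deg = x_deg, y_deg = y_deg,
       pupil = cyc$p,
       pupil_smooth = smooth_pupil(cyc$p, cfg$pupil_smooth_window_ms, dt_ms),
       blinks = blinks, fixations = fixes, dt_ms = dt_ms)
}
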