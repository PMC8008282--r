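# Pupillometric indices: baseline computation, baseline change in pupil
# diameter (BCPD) and the Low/High Index of Pupillary Activity (LHIPA).
#
# LHIPA summarises pupil oscillatory structure as the duration-normalised
# count of thresholded modulus maxima of the ratio between low- and
# high-frequency wavelet detail coefficients of the pupil trace; it decreases
# with increased cognitive effort (more high-frequency content). The discrete
# wavelet transform (periodized pyramid algorithm with Symlet-16 analysis
# filters) is implemented here because the index needs nothing more than
# cascaded analysis filtering.

# Symlet-16 analysis (decomposition) filters; standard published constants.
SYM16_DEC_LO <- c(
  6.230006701220761e-06, -3.113556407621969e-06, -1.0943147929529757e-04,
  2.8078582128442894e-05, 8.523547108047095e-04, -1.084456223089688e-04,
  -3.8809122526038786e-03, 7.182119788317892e-04, 1.2666731659857348e-02,
  -3.1265171722710075e-03, -3.1051202843553064e-02, 4.869274404904607e-03,
  3.2333091610663785e-02, -6.698304907021778e-02, -3.4574228416972504e-02,
  3.9712293362064416e-01, 7.565249878756971e-01, 4.7534280601152273e-01,
  -5.4040601387606135e-02, -1.5959219218520598e-01, 3.072113906330156e-02,
  7.803785290341991e-02, -3.510275068374009e-03, -2.4952758046290123e-02,
  1.359844742484172e-03, 6.9377611308027096e-03, -2.2211647621176323e-04,
  -1.3387206066921965e-03, 3.656592483348223e-05, 1.6545679579108483e-04,
  -5.396483179315242e-06, -1.0797982104319795e-05)

SYM16_DEC_HI <- rev(SYM16_DEC_LO) * rep(c(-1, 1), 16)

# One periodized analysis step (circular convolution, downsample by two):
# y[k] = sum_j f[j] * x[(2k + L/2 - j) mod n], j and k zero-based.
# Odd-length inputs are extended by repeating the last sample.
dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }
  L <- length(filt)
  k <- seq_len(n %/% 2L) - 1L
  y <- numeric(n %/% 2L)
  for (j in seq_along(filt)) {
    idx <- (2L * k + L %/% 2L - j + 1L) %% n + 1L
    y <- y + filt[j] * x[idx]
  }
  y
}

# Maximum useful decomposition depth for signal length n and filter length L.
dwt_max_level <- function(n, L = length(SYM16_DEC_LO)) {
  if (n < L) return(0L)
  as.integer(floor(log2(n / (L - 1))))
}

# Detail coefficients at `level`: cascade the approximation path level-1
# times, then one high-pass step.
dwt_detail <- function(x, level) {
  for (i in seq_len(level - 1L)) x <- dwt_step(x, SYM16_DEC_LO)
  dwt_step(x, SYM16_DEC_HI)
}

#' LHIPA parameters
#'
#' @param wavelet analysis wavelet (only `"sym16"` is shipped).
#' @param hf_level decomposition level of the high-frequency band (default 1).
#' @param lf_level_rule rule for the low-frequency band level; only
#'   `"half_max_depth"` (half the maximal decomposition depth for the slice
#'   length) is implemented.
#' @param threshold_rule maxima threshold rule; only `"universal"`
#'   (`sigma_hat * sqrt(2 log n)`) is implemented.
#' @param max_missing_frac slices with a larger missing fraction yield NA
#'   with a warning.
#' @return An object of class `pupil_index_config`.
#' @export
pupil_index_config <- function(wavelet = "sym16", hf_level = 1L,
                               lf_level_rule = "half_max_depth",
                               threshold_rule = "universal",
                               max_missing_frac = 0.3) {
  if (!identical(wavelet, "sym16"))
    stop_oe("only the sym16 wavelet is shipped", class = "oe_validation_error")
  if (!identical(lf_level_rule, "half_max_depth") ||
      !identical(threshold_rule, "universal"))
    stop_oe("unsupported lf_level_rule/threshold_rule", class = "oe_validation_error")
  structure(list(wavelet = wavelet, hf_level = as.integer(hf_level),
                 lf_level_rule = lf_level_rule, threshold_rule = threshold_rule,
                 max_missing_frac = max_missing_frac),
            class = "pupil_index_config")
}

#' Pupil baseline from training trials
#'
#' Mean of the smoothed, blink-masked cyclopean pupil pooled across all
#' training trials of one participant (pooling weights each sample equally,
#' so longer trials weigh more).
#'
#' @param recordings list of training `gaze_recording`s for one participant.
#' @param cfg a `preprocess_config`.
#' @param min_samples minimum usable samples (default 100).
#' @return An object of class `pupil_baseline` with `participant_id`,
#'   `baseline_value`, `n_samples_used`.
#' @export
compute_baseline <- function(recordings, cfg = preprocess_config(),
                             min_samples = 100) {
  if (!length(recordings))
    stop_oe("no training recordings", class = "oe_insufficient_data")
  vals <- unlist(lapply(recordings, function(rec) {
    blinks <- detect_blinks(rec, cfg$blink_pad_ms)
    masked <- mask_blinks(rec, blinks)
    cyc <- average_eyes(masked)
    dt_ms <- if (length(rec$t) > 1) stats::median(diff(rec$t)) else 1
    sm <- smooth_pupil(cyc$p, cfg$pupil_smooth_window_ms, dt_ms)
    sm[!is.na(sm)]
  }))
  if (length(vals) < min_samples)
    stop_oe("fewer than ", min_samples, " usable pupil samples in training trials",
            class = "oe_insufficient_data")
  structure(list(participant_id = recordings[[1]]$participant_id,
                 baseline_value = mean(vals),
                 n_samples_used = length(vals)),
            class = "pupil_baseline")
}

#' @export
print.pupil_baseline <- function(x, ...) {
  cat(sprintf("<pupil_baseline> participant %s: %.2f (n = %d samples)\n",
              x$participant_id, x$baseline_value, x$n_samples_used))
  invisible(x)
}

#' Baseline change in pupil diameter (BCPD) for one epoch
#'
#' Mean of the smoothed epoch pupil minus the training baseline; positive
#' values mean dilation relative to baseline.
#'
#' @param pupil_slice smoothed pupil samples of one cue epoch.
#' @param baseline a `pupil_baseline` (or a bare numeric baseline value).
#' @param min_samples minimum non-missing samples; below it the value is NA
#'   with a warning.
#' @return BCPD in arbitrary units, or NA.
#' @export
bcpd <- function(pupil_slice, baseline, min_samples = 100) {
  b <- if (inherits(baseline, "pupil_baseline")) baseline$baseline_value else baseline
  ok <- !is.na(pupil_slice)
  if (sum(ok) < min_samples) {
    warning("epoch has fewer than ", min_samples,
            " usable pupil samples; BCPD set to NA")
    return(NA_real_)
  }
  mean(pupil_slice[ok]) - b
}

#' Low/High Index of Pupillary Activity (LHIPA) for one epoch
#'
#' Pipeline: (1) discrete wavelet decomposition of the slice (sym16,
#' periodized); (2) detail coefficients at the high-frequency level (1) and
#' at the low-frequency level (half the maximal decomposition depth for this
#' slice length); (3) amplitude normalisation of each set by `2^(level/2)`;
#' (4) the sparser low-frequency coefficients are aligned to the
#' high-frequency grid and the low/high ratio series formed; (5) modulus
#' maxima of the ratio (samples whose absolute value strictly exceeds both
#' neighbours); (6) the universal threshold `sigma_hat * sqrt(2 log n)`
#' suppresses large-amplitude maxima (artifact rejection) — maxima at or
#' below the threshold survive; (7) LHIPA = surviving-maxima count divided by
#' slice duration in seconds.
#'
#' Missing samples are linearly interpolated first (wavelet analysis needs a
#' gapless signal); slices missing more than `max_missing_frac` yield NA with
#' a warning.
#'
#' @param pupil_slice pupil samples of one cue epoch (unsmoothed; smoothing
#'   would remove the high-frequency band the index measures).
#' @param dt sampling interval in seconds.
#' @param cfg a `pupil_index_config`.
#' @return LHIPA in 1/s, or NA for an over-gappy slice.
#' @export
lhipa <- function(pupil_slice, dt = 1e-3, cfg = pupil_index_config()) {
  n <- length(pupil_slice)
  miss <- is.na(pupil_slice)
  if (all(miss)) {
    warning("all pupil samples missing; LHIPA set to NA")
    return(NA_real_)
  }
  if (mean(miss) > cfg$max_missing_frac) {
    warning("more than ", round(100 * cfg$max_missing_frac),
            "% of the slice missing; LHIPA set to NA")
    return(NA_real_)
  }
  if (any(miss)) {
    idx <- seq_len(n)
    pupil_slice <- stats::approx(idx[!miss], pupil_slice[!miss], xout = idx,
                                 rule = 2)$y
  }
  maxlev <- dwt_max_level(n)
  lof <- maxlev %/% 2L
  hif <- cfg$hf_level
  if (lof <= hif)
    stop_oe("slice too short for two separated decomposition levels",
            class = "oe_insufficient_data")
  cd_h <- dwt_detail(pupil_slice, hif) / sqrt(2^hif)
  cd_l <- dwt_detail(pupil_slice, lof) / sqrt(2^lof)
  # align the sparser low-frequency coefficients to the high-frequency grid
  stride <- 2^(lof - hif)
  h_idx <- pmin((seq_along(cd_l) - 1L) * stride + 1L, length(cd_h))
  denom <- cd_h[h_idx]
  eps <- 1e-12 * max(abs(cd_h), 1e-300)
  denom[abs(denom) < eps] <- eps
  ratio <- cd_l / denom
  mm <- modulus_maxima(ratio)
  lam <- stats::sd(mm) * sqrt(2 * log(length(mm)))
  surviving <- sum(mm > 0 & mm <= lam)
  surviving / (n * dt)
}

# Modulus maxima: |d[i]| strictly exceeding both neighbours; endpoints never
# qualify. Returns the magnitude at maxima, 0 elsewhere.
modulus_maxima <- function(d) {
  m <- abs(d)
  n <- length(m)
  out <- numeric(n)
  if (n >= 3) {
    i <- 2:(n - 1)
    is_max <- m[i] > m[i - 1] & m[i] > m[i + 1]
    out[i][is_max] <- m[i][is_max]
  }
  out
}
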