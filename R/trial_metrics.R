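# Cue-epoch segmentation, per-epoch metrics (BCPD, LHIPA, MS rate/magnitude)
# and the per-trial differential (delta) measures that feed the mixed models.

#' Segment a recording into cue-epoch slices
#'
#' @param trial_row one row of a trial table.
#' @param pre preprocessed recording from [preprocess_recording()].
#' @return data.frame with `epoch_index`, `onset_ms`, `offset_ms`,
#'   `start_idx`, `end_idx` (sample indices into the recording).
#' @export
segment_cue_epochs <- function(trial_row, pre) {
  ep <- trial_epochs(trial_row)
  t0 <- pre$t[1]
  t1 <- pre$t[length(pre$t)]
  if (min(ep$onset_ms) < t0 || max(ep$offset_ms) > t1 + pre$dt_ms)
    stop_oe("epoch boundary outside recording span in trial ", trial_row$trial,
            " of participant ", trial_row$participant, class = "oe_validation_error")
  ep$start_idx <- vapply(ep$onset_ms, function(o) which(pre$t >= o)[1], integer(1))
  ep$end_idx <- vapply(ep$offset_ms, function(o) {
    w <- which(pre$t < o); w[length(w)]
  }, integer(1))
  ep
}

#' Per-epoch eye-movement metrics for one trial
#'
#' @param trial_row one row of a trial table.
#' @param pre preprocessed recording.
#' @param events detected microsaccades for the trial (absolute times).
#' @param baseline a `pupil_baseline` for the participant.
#' @param pupil_cfg a `pupil_index_config`.
#' @param measures subset of `c("bcpd", "lhipa", "ms_rate", "ms_magnitude")`
#'   to compute; unrequested metrics come back NA. Restricting the set is a
#'   compute-time convenience, not an analysis choice.
#' @return data.frame with one row per cue epoch; failures yield NA values,
#'   never dropped rows.
#' @export
compute_epoch_metrics <- function(trial_row, pre, events, baseline,
                                  pupil_cfg = pupil_index_config(),
                                  measures = c("bcpd", "lhipa", "ms_rate",
                                               "ms_magnitude")) {
  ep <- segment_cue_epochs(trial_row, pre)
  want_ms <- any(c("ms_rate", "ms_magnitude") %in% measures)
  ms <- if (want_ms) epoch_summaries(events, ep) else NULL
  res <- lapply(seq_len(nrow(ep)), function(i) {
    idx <- ep$start_idx[i]:ep$end_idx[i]
    b <- l <- NA_real_
    if ("bcpd" %in% measures)
      b <- tryCatch(suppressWarnings(bcpd(pre$pupil_smooth[idx], baseline)),
                    error = function(e) NA_real_)
    if ("lhipa" %in% measures)
      l <- tryCatch(suppressWarnings(lhipa(pre$pupil[idx], pre$dt_ms / 1000,
                                           pupil_cfg)),
                    error = function(e) NA_real_)
    data.frame(participant = trial_row$participant,
               condition = trial_row$condition,
               trial = trial_row$trial,
               epoch_index = ep$epoch_index[i],
               bcpd = b, lhipa = l,
               ms_rate = if ("ms_rate" %in% measures) ms$ms_rate[i] else NA_real_,
               ms_magnitude = if ("ms_magnitude" %in% measures) ms$ms_magnitude[i]
                              else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-trial differential (delta) measures
#'
#' For each trial and each metric, the value during the last acquired cue
#' minus the value during the first: positive `d_bcpd` means the pupil
#' dilated over the trial. Single-cue trials have every delta equal to 0 by
#' construction (last epoch = first epoch); they are retained because the
#' cue-count regressor spans 1..6. Multi-cue deltas are NA when either
#' endpoint metric is missing.
#'
#' @param metrics epoch-metric table from [compute_epoch_metrics()] rows
#'   (possibly many trials).
#' @return data.frame with one row per trial: `participant`, `condition`,
#'   `trial`, `n_cues`, `d_bcpd`, `d_lhipa`, `d_ms_rate`, `d_ms_magnitude`.
#' @export
compute_deltas <- function(metrics) {
  keys <- key_pt(metrics$participant, metrics$trial)
  res <- lapply(split(seq_len(nrow(metrics)), factor(keys, levels = unique(keys))),
                function(idx) {
    g <- metrics[idx, ]
    g <- g[order(g$epoch_index), ]
    n_cues <- nrow(g)
    d <- function(col) {
      if (n_cues == 1) return(0)
      g[[col]][n_cues] - g[[col]][1]
    }
    data.frame(participant = g$participant[1], condition = g$condition[1],
               trial = g$trial[1], n_cues = n_cues,
               d_bcpd = d("bcpd"), d_lhipa = d("lhipa"),
               d_ms_rate = d("ms_rate"), d_ms_magnitude = d("ms_magnitude"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Epoch metrics for a whole dataset
#'
#' Per participant: the pupil baseline is computed from the training trials,
#' then every main (non-training) trial is preprocessed, its microsaccades
#' detected within fixations, and per-epoch metrics assembled.
#'
#' @param ds an `experiment_dataset`.
#' @param pre_cfg a `preprocess_config`.
#' @param det_cfg a `detector_config`.
#' @param pupil_cfg a `pupil_index_config`.
#' @param measures metric subset, as in [compute_epoch_metrics()].
#' @return List with `metrics` (epoch-level table), `deltas` (trial-level
#'   table), `events` (all detected microsaccades with participant/trial),
#'   `baselines` (per-participant).
#' @export
compute_dataset_metrics <- function(ds, pre_cfg = preprocess_config(),
                                    det_cfg = detector_config(),
                                    pupil_cfg = pupil_index_config(),
                                    measures = c("bcpd", "lhipa", "ms_rate",
                                                 "ms_magnitude")) {
  trials <- ds$trials
  want_ms <- any(c("ms_rate", "ms_magnitude") %in% measures)
  metrics <- list(); all_events <- list(); baselines <- list()
  for (p in unique(trials$participant)) {
    tr_p <- trials[trials$participant == p, ]
    train_keys <- key_pt(p, tr_p$trial[tr_p$is_training])
    baseline <- compute_baseline(ds$recordings[train_keys], pre_cfg)
    baselines[[p]] <- data.frame(participant = p,
                                 baseline = baseline$baseline_value,
                                 n_samples = baseline$n_samples_used)
    for (i in which(!tr_p$is_training)) {
      row <- tr_p[i, ]
      rec <- ds$recordings[[key_pt(p, row$trial)]]
      pre <- preprocess_recording(rec, ds$geometry, pre_cfg, fixations = want_ms)
      ev <- if (want_ms) detect_trial_microsaccades(pre, det_cfg) else
        data.frame(onset_ms = numeric(), magnitude_deg = numeric())
      metrics[[length(metrics) + 1L]] <-
        compute_epoch_metrics(row, pre, ev, baseline, pupil_cfg, measures)
      if (nrow(ev) && want_ms) {
        ev$participant <- p; ev$trial <- row$trial
        all_events[[length(all_events) + 1L]] <- ev
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  list(metrics = metrics,
       deltas = compute_deltas(metrics),
       events = if (length(all_events)) do.call(rbind, all_events) else NULL,
       baselines = do.call(rbind, baselines))
}
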