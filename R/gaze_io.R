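# Data model and delimited-text interchange for gaze recordings and trials.
#
# Conventions used throughout the package (declared once, inherited everywhere):
# gaze coordinates are screen pixels with origin at the top-left corner and y
# growing downward; timestamps are milliseconds; pupil size is in arbitrary
# tracker units. Missing data are explicit NAs, never sentinel values, except
# that pupil == 0 on input is coerced to NA (closed-eye convention of common
# video trackers).

#' Experimental conditions recognised by the pipeline
#' @export
CONDITIONS <- c("neutral", "aversive", "erotic")

SAMPLE_COLUMNS <- c("participant", "trial", "t", "xl", "yl", "xr", "yr", "pl", "pr")
TRIAL_COLUMNS <- c("participant", "condition", "trial", "is_training", "n_cues",
                   "cue_onsets", "cue_offsets", "choice", "accuracy")

#' Screen geometry of the recording setup
#'
#' Physical and pixel dimensions of the stimulus screen plus viewing distance,
#' needed to convert pixel gaze coordinates to degrees of visual angle. The
#' physical size must be given explicitly; it is never inferred from a diagonal.
#'
#' @param distance_cm viewing distance from eye to screen (cm).
#' @param screen_width_px,screen_height_px screen resolution (pixels).
#' @param screen_width_cm,screen_height_cm physical screen size (cm).
#' @return An object of class `screen_geometry`.
#' @details A warning is raised when the pixel pitch (cm per pixel) differs
#'   between axes by more than 5%, which usually indicates a mistyped physical
#'   size (square pixels are the norm on LCD panels).
#' @examples
#' geom <- screen_geometry(57, 1024, 768, 44.7, 33.5)
#' @export
screen_geometry <- function(distance_cm, screen_width_px, screen_height_px,
                            screen_width_cm, screen_height_cm) {
  assert_scalar_num(distance_cm, "distance_cm", positive = TRUE)
  assert_scalar_num(screen_width_px, "screen_width_px", positive = TRUE)
  assert_scalar_num(screen_height_px, "screen_height_px", positive = TRUE)
  assert_scalar_num(screen_width_cm, "screen_width_cm", positive = TRUE)
  assert_scalar_num(screen_height_cm, "screen_height_cm", positive = TRUE)
  pitch_x <- screen_width_cm / screen_width_px
  pitch_y <- screen_height_cm / screen_height_px
  if (abs(pitch_x - pitch_y) / max(pitch_x, pitch_y) > 0.05)
    warning("pixel pitch differs between axes by more than 5%; check the physical screen size")
  structure(list(distance_cm = distance_cm,
                 screen_width_px = screen_width_px,
                 screen_height_px = screen_height_px,
                 screen_width_cm = screen_width_cm,
                 screen_height_cm = screen_height_cm),
            class = "screen_geometry")
}

#' Default screen geometry
#'
#' A 22-inch 4:3 LCD panel at 1024x768 viewed from 57 cm, the canonical
#' psychophysics distance at which 1 cm on screen subtends about 1 degree.
#' @return A `screen_geometry`.
#' @export
default_geometry <- function() {
  screen_geometry(distance_cm = 57, screen_width_px = 1024, screen_height_px = 768,
                  screen_width_cm = 44.7, screen_height_cm = 33.5)
}

#' Specification of the cue-based decision task
#'
#' Trial timing and cue structure of the two-alternative multi-attribute
#' decision task: a fixation cross, an affective prime, then up to
#' `n_cues_max` sequentially acquired cues ordered by decreasing validity.
#'
#' @param n_cues_max maximum number of cues (default 6).
#' @param cue_validities probability that each cue, when it discriminates,
#'   points to the correct alternative; strictly decreasing, each in (0.5, 1).
#' @param fixation_ms,prime_ms,first_cue_ms durations of the fixation cross,
#'   affective prime, and the (fixed-duration) first cue epoch, in ms.
#' @param n_trials number of main decision trials per participant.
#' @param n_training number of training trials (used as pupil baseline).
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(n_cues_max = 6L,
                      cue_validities = c(0.706, 0.688, 0.667, 0.647, 0.625, 0.62),
                      fixation_ms = 1000, prime_ms = 3000, first_cue_ms = 2000,
                      n_trials = 24L, n_training = 3L) {
  if (length(cue_validities) != n_cues_max)
    stop_oe("cue_validities must have length n_cues_max", class = "oe_validation_error")
  if (any(diff(cue_validities) >= 0))
    stop_oe("cue_validities must be strictly decreasing", class = "oe_validation_error")
  if (any(cue_validities <= 0.5 | cue_validities >= 1))
    stop_oe("cue_validities must lie in (0.5, 1)", class = "oe_validation_error")
  for (nm in c("fixation_ms", "prime_ms", "first_cue_ms"))
    assert_scalar_num(get(nm), nm, positive = TRUE)
  structure(list(n_cues_max = as.integer(n_cues_max),
                 cue_validities = cue_validities,
                 fixation_ms = fixation_ms, prime_ms = prime_ms,
                 first_cue_ms = first_cue_ms,
                 n_trials = as.integer(n_trials),
                 n_training = as.integer(n_training)),
            class = "task_spec")
}

#' Per-trial binocular gaze/pupil recording
#'
#' Container for one trial of binocular samples at a nominal 1000 Hz.
#' All channels have equal length; timestamps are strictly increasing and the
#' median inter-sample interval must be within 10% of 1 ms. Pupil values of 0
#' are coerced to NA (closed eye).
#'
#' @param participant_id,trial_id identifiers.
#' @param t timestamps in ms.
#' @param xl,yl,xr,yr left/right gaze coordinates in pixels (NA allowed).
#' @param pl,pr left/right pupil size in arbitrary units (NA or >= 0).
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(participant_id, trial_id, t, xl, yl, xr, yr, pl, pr) {
  n <- length(t)
  chans <- list(xl = xl, yl = yl, xr = xr, yr = yr, pl = pl, pr = pr)
  for (nm in names(chans))
    if (length(chans[[nm]]) != n)
      stop_oe("channel ", nm, " length differs from t (trial ", trial_id, ")",
              class = "oe_validation_error")
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0))
      stop_oe("timestamps not strictly increasing in trial ", trial_id,
              " of participant ", participant_id, class = "oe_validation_error")
    if (abs(stats::median(dt) - 1) > 0.1)
      stop_oe("median inter-sample interval off the nominal 1 ms by more than 10% ",
              "(trial ", trial_id, ")", class = "oe_validation_error")
  }
  pl[!is.na(pl) & pl == 0] <- NA_real_
  pr[!is.na(pr) & pr == 0] <- NA_real_
  if (any(pl < 0, na.rm = TRUE) || any(pr < 0, na.rm = TRUE))
    stop_oe("negative pupil values in trial ", trial_id, class = "oe_validation_error")
  structure(list(participant_id = as.character(participant_id),
                 trial_id = as.integer(trial_id),
                 t = as.numeric(t),
                 xl = as.numeric(xl), yl = as.numeric(yl),
                 xr = as.numeric(xr), yr = as.numeric(yr),
                 pl = as.numeric(pl), pr = as.numeric(pr)),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> participant %s, trial %d: %d samples (%.0f-%.0f ms)\n",
              x$participant_id, x$trial_id, length(x$t),
              if (length(x$t)) min(x$t) else NA, if (length(x$t)) max(x$t) else NA))
  invisible(x)
}

#' One trial-event record
#'
#' @param participant_id participant identifier.
#' @param condition one of `CONDITIONS`.
#' @param trial_id trial index.
#' @param is_training logical flag; training trials feed the pupil baseline.
#' @param cue_onsets,cue_offsets epoch boundaries in ms, one pair per acquired
#'   cue, increasing and non-overlapping.
#' @param choice "A" or "B".
#' @param accuracy 0 or 1.
#' @return A one-row data.frame in the canonical trial-table layout; epoch
#'   boundary lists are stored as ";"-joined integers.
#' @export
trial_record <- function(participant_id, condition, trial_id, is_training,
                         cue_onsets, cue_offsets, choice, accuracy) {
  check_condition(condition)
  n_cues <- length(cue_onsets)
  if (length(cue_offsets) != n_cues)
    stop_oe("cue_onsets and cue_offsets lengths differ", class = "oe_validation_error")
  if (n_cues < 1L || n_cues > 6L)
    stop_oe("n_cues must be between 1 and 6", class = "oe_validation_error")
  if (any(cue_offsets <= cue_onsets))
    stop_oe("each cue epoch must have offset > onset", class = "oe_validation_error")
  if (n_cues > 1 && any(cue_onsets[-1] < cue_offsets[-n_cues]))
    stop_oe("cue epochs must be increasing and non-overlapping", class = "oe_validation_error")
  if (!choice %in% c("A", "B"))
    stop_oe("choice must be \"A\" or \"B\"", class = "oe_validation_error")
  if (!accuracy %in% c(0, 1))
    stop_oe("accuracy must be 0 or 1", class = "oe_validation_error")
  data.frame(participant = as.character(participant_id),
             condition = condition,
             trial = as.integer(trial_id),
             is_training = as.logical(is_training),
             n_cues = as.integer(n_cues),
             cue_onsets = paste(as.integer(round(cue_onsets)), collapse = ";"),
             cue_offsets = paste(as.integer(round(cue_offsets)), collapse = ";"),
             choice = choice,
             accuracy = as.integer(accuracy),
             stringsAsFactors = FALSE)
}

check_condition <- function(condition) {
  if (length(condition) != 1L || !condition %in% CONDITIONS)
    stop_oe("unknown condition ", deparse(condition),
            "; allowed labels: ", paste(CONDITIONS, collapse = ", "),
            class = "oe_validation_error")
  invisible(condition)
}

#' Parse the ";"-joined epoch boundaries of one trial row
#'
#' @param trial_row one row of a trial table.
#' @return A data.frame with `epoch_index`, `onset_ms`, `offset_ms`.
#' @export
trial_epochs <- function(trial_row) {
  on <- as.numeric(strsplit(trial_row$cue_onsets, ";", fixed = TRUE)[[1]])
  off <- as.numeric(strsplit(trial_row$cue_offsets, ";", fixed = TRUE)[[1]])
  data.frame(epoch_index = seq_along(on), onset_ms = on, offset_ms = off)
}

#' Bundle geometry, task, recordings and trials into one dataset
#'
#' @param geometry a `screen_geometry`.
#' @param task a `task_spec`.
#' @param recordings named list of `gaze_recording` keyed "participant:trial".
#' @param trials trial table (as from [read_trials()] or [trial_record()]).
#' @param truth optional ground-truth ledger from the synthetic generator.
#' @return An object of class `experiment_dataset`.
#' @export
experiment_dataset <- function(geometry, task, recordings, trials, truth = NULL) {
  stopifnot(inherits(geometry, "screen_geometry"), inherits(task, "task_spec"))
  structure(list(geometry = geometry, task = task,
                 recordings = recordings, trials = trials, truth = truth),
            class = "experiment_dataset")
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat(sprintf("<experiment_dataset> %d participants, %d trials (%d training), %d recordings\n",
              length(unique(x$trials$participant)), nrow(x$trials),
              sum(x$trials$is_training), length(x$recordings)))
  invisible(x)
}

#' Read per-trial gaze samples from a delimited text file
#'
#' The file must be comma-delimited with header
#' `participant,trial,t,xl,yl,xr,yr,pl,pr`; "NA" or empty fields are missing.
#' One `gaze_recording` is built per (participant, trial) group, in file order.
#'
#' @param path file path.
#' @param geometry optional `screen_geometry` attached as an attribute.
#' @return Named list of `gaze_recording` keyed "participant:trial".
#' @export
read_samples <- function(path, geometry = NULL) {
  if (!file.exists(path)) stop_oe("file not found: ", path, class = "oe_format_error")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), SAMPLE_COLUMNS))
    stop_oe("malformed samples header; expected: ",
            paste(SAMPLE_COLUMNS, collapse = ","), class = "oe_format_error")
  df <- utils::read.csv(path, na.strings = c("NA", ""), stringsAsFactors = FALSE)
  df$participant <- as.character(df$participant)
  keys <- key_pt(df$participant, df$trial)
  groups <- split(seq_len(nrow(df)), factor(keys, levels = unique(keys)))
  recs <- lapply(groups, function(idx) {
    g <- df[idx, , drop = FALSE]
    gaze_recording(g$participant[1], g$trial[1], g$t,
                   g$xl, g$yl, g$xr, g$yr, g$pl, g$pr)
  })
  names(recs) <- names(groups)
  if (!is.null(geometry)) attr(recs, "geometry") <- geometry
  recs
}

#' Write gaze recordings to the delimited interchange format
#'
#' @param recordings list of `gaze_recording`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_samples <- function(recordings, path) {
  dfs <- lapply(recordings, function(r)
    data.frame(participant = r$participant_id, trial = r$trial_id, t = r$t,
               xl = r$xl, yl = r$yl, xr = r$xr, yr = r$yr, pl = r$pl, pr = r$pr,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, dfs)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial-event table
#'
#' @param path file path to a comma-delimited trial table with header
#'   `participant,condition,trial,is_training,n_cues,cue_onsets,cue_offsets,choice,accuracy`.
#' @return A validated trial data.frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop_oe("file not found: ", path, class = "oe_format_error")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), TRIAL_COLUMNS))
    stop_oe("malformed trials header; expected: ",
            paste(TRIAL_COLUMNS, collapse = ","), class = "oe_format_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant = "character",
                                       cue_onsets = "character",
                                       cue_offsets = "character"))
  df$is_training <- as.logical(df$is_training)
  validate_trials(df)
  df
}

validate_trials <- function(df) {
  for (i in seq_len(nrow(df))) {
    check_condition(df$condition[i])
    ep <- trial_epochs(df[i, ])
    if (nrow(ep) != df$n_cues[i])
      stop_oe("n_cues does not match epoch count in trial ", df$trial[i],
              " of participant ", df$participant[i], class = "oe_validation_error")
    if (any(ep$offset_ms <= ep$onset_ms) ||
        (nrow(ep) > 1 && any(ep$onset_ms[-1] < ep$offset_ms[-nrow(ep)])))
      stop_oe("epochs not increasing/non-overlapping in trial ", df$trial[i],
              class = "oe_validation_error")
  }
  cond_by_p <- tapply(df$condition, df$participant, function(z) length(unique(z)))
  if (any(cond_by_p > 1))
    stop_oe("participant assigned to more than one condition: ",
            paste(names(cond_by_p)[cond_by_p > 1], collapse = ", "),
            class = "oe_validation_error")
  invisible(df)
}

#' Write a trial-event table
#'
#' @param trials trial data.frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Consistency report for an experiment dataset
#'
#' Reporting-only operation: lists every cross-reference violation with
#' participant/trial coordinates. An empty report means the dataset is
#' consistent.
#'
#' @param ds an `experiment_dataset`.
#' @return A data.frame with columns `participant`, `trial`, `issue`
#'   (zero rows when consistent).
#' @export
validate_dataset <- function(ds) {
  issues <- list()
  add <- function(participant, trial, issue)
    issues[[length(issues) + 1L]] <<- data.frame(
      participant = participant, trial = trial, issue = issue,
      stringsAsFactors = FALSE)
  trial_keys <- key_pt(ds$trials$participant, ds$trials$trial)
  rec_keys <- names(ds$recordings)
  for (i in seq_len(nrow(ds$trials))) {
    if (!trial_keys[i] %in% rec_keys)
      add(ds$trials$participant[i], ds$trials$trial[i], "orphan trial: no matching recording")
  }
  for (k in setdiff(rec_keys, trial_keys)) {
    r <- ds$recordings[[k]]
    add(r$participant_id, r$trial_id, "orphan recording: no matching trial")
  }
  if (sum(duplicated(trial_keys)) > 0)
    for (k in unique(trial_keys[duplicated(trial_keys)]))
      add(sub(":.*$", "", k), as.integer(sub("^.*:", "", k)), "duplicated trial key")
  cond_by_p <- tapply(ds$trials$condition, ds$trials$participant,
                      function(z) length(unique(z)))
  for (p in names(cond_by_p)[cond_by_p > 1])
    add(p, NA_integer_, "condition conflict: participant in multiple conditions")
  # epoch boundaries must sit inside the recording span
  for (i in seq_len(nrow(ds$trials))) {
    k <- trial_keys[i]
    if (!k %in% rec_keys) next
    r <- ds$recordings[[k]]
    ep <- trial_epochs(ds$trials[i, ])
    if (length(r$t) && (min(ep$onset_ms) < min(r$t) || max(ep$offset_ms) > max(r$t) + 1))
      add(ds$trials$participant[i], ds$trials$trial[i],
          "epoch boundary outside recording span")
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(participant = character(), trial = integer(), issue = character(),
                  stringsAsFactors = FALSE)
}
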