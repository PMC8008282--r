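# YAML configuration: one file carries geometry, task, simulation effects and
# the preprocessing/detector/pupil-index knobs, so a whole run is reproducible
# from a config plus a seed.

#' Default pipeline configuration
#'
#' Nested list with blocks `geometry`, `task`, `simulation`, `effects`,
#' `preprocess`, `detector` and `pupil_index`, mirroring the YAML layout
#' written by [write_config()].
#' @return A nested list.
#' @export
default_config <- function() {
  geom <- default_geometry()
  task <- task_spec()
  eff <- effect_params()
  # matrices do not survive YAML: store per-condition probability vectors
  eff$cue_count_probs <- lapply(stats::setNames(CONDITIONS, CONDITIONS),
                                function(cc) unname(eff$cue_count_probs[cc, ]))
  eff$ms_rate_slope_per_cue <- as.list(eff$ms_rate_slope_per_cue)
  eff$bcpd_slope_per_cue <- as.list(eff$bcpd_slope_per_cue)
  list(
    geometry = unclass(geom),
    task = unclass(task),
    simulation = list(
      n_participants_per_condition = list(neutral = 8L, aversive = 7L, erotic = 6L),
      seed = 1L),
    effects = unclass(eff),
    preprocess = unclass(preprocess_config()),
    detector = unclass(detector_config()),
    pupil_index = unclass(pupil_index_config())
  )
}

#' Read a pipeline configuration from YAML
#'
#' Blocks missing from the file fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A config list as from [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_oe("config file not found: ", path, class = "oe_format_error")
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (block in names(cfg)) {
    if (!is.null(user[[block]])) {
      for (nm in names(user[[block]])) cfg[[block]][[nm]] <- user[[block]][[nm]]
    }
  }
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg config list.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname config_simulation
#' @export
config_geometry <- function(cfg) do.call(screen_geometry, cfg$geometry[names(formals(screen_geometry))])

#' @rdname config_simulation
#' @export
config_task <- function(cfg) {
  f <- cfg$task
  task_spec(n_cues_max = f$n_cues_max, cue_validities = as.numeric(f$cue_validities),
            fixation_ms = f$fixation_ms, prime_ms = f$prime_ms,
            first_cue_ms = f$first_cue_ms, n_trials = f$n_trials,
            n_training = f$n_training)
}

#' @rdname config_simulation
#' @export
config_effects <- function(cfg) {
  e <- cfg$effects
  e$cue_count_probs <- as_cue_prob_matrix(e$cue_count_probs)
  do.call(effect_params, e[names(formals(effect_params))[names(formals(effect_params)) %in% names(e)]])
}

#' @rdname config_simulation
#' @export
config_preprocess <- function(cfg) do.call(preprocess_config, cfg$preprocess)

#' @rdname config_simulation
#' @export
config_detector <- function(cfg) do.call(detector_config, cfg$detector)

#' @rdname config_simulation
#' @export
config_pupil_index <- function(cfg) do.call(pupil_index_config, cfg$pupil_index)

#' Build a simulation configuration from a pipeline config
#'
#' @param cfg config list as from [default_config()] / [read_config()].
#' @param seed optional integer overriding `cfg$simulation$seed`.
#' @return A `simulation_config`.
#' @export
config_simulation <- function(cfg, seed = NULL) {
  npc <- unlist(cfg$simulation$n_participants_per_condition)
  simulation_config(
    n_participants_per_condition = npc[CONDITIONS],
    task = config_task(cfg),
    geometry = config_geometry(cfg),
    effects = config_effects(cfg),
    seed = seed %||% cfg$simulation$seed)
}
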