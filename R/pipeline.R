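# End-to-end orchestration: simulate (or load) -> preprocess -> detect ->
# metrics -> models -> report bundle.

#' Run the full analysis pipeline
#'
#' Executes every stage on a dataset (simulated from the configuration when
#' none is given) and assembles the report: cue-count distribution with
#' per-condition goodness-of-fit tests against equal proportions,
#' participant-level correlations, the main-sequence regression, and the four
#' nested LMMs (delta BCPD, delta LHIPA, MS rate, MS magnitude).
#'
#' @param config pipeline configuration list (see [default_config()]).
#' @param dataset optional `experiment_dataset`; simulated when NULL.
#' @param seed integer seed used when simulating.
#' @param out_dir optional directory; when given, CSV tables and a JSON
#'   summary are written into it.
#' @param measures metric subset to compute (see [compute_epoch_metrics()]);
#'   LMMs are fitted only for available measures.
#' @param ms_rate_dv `"delta"` (default) analyses the per-trial change in
#'   microsaccade rate between last and first cue; `"epoch"` analyses raw
#'   per-epoch rates instead.
#' @param verbose print stage progress to stderr.
#' @return An object of class `effort_report`.
#' @export
run_pipeline <- function(config = default_config(), dataset = NULL, seed = NULL,
                         out_dir = NULL,
                         measures = c("bcpd", "lhipa", "ms_rate", "ms_magnitude"),
                         ms_rate_dv = c("delta", "epoch"), verbose = FALSE) {
  ms_rate_dv <- match.arg(ms_rate_dv)
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  if (is.null(dataset)) {
    say("simulating dataset")
    dataset <- generate_dataset(config_simulation(config, seed))
  }
  pre_cfg <- config_preprocess(config)
  det_cfg <- config_detector(config)
  pup_cfg <- config_pupil_index(config)

  say("computing per-epoch metrics for %d trials", sum(!dataset$trials$is_training))
  mets <- compute_dataset_metrics(dataset, pre_cfg, det_cfg, pup_cfg, measures)

  main_trials <- dataset$trials[!dataset$trials$is_training, ]

  # --- cue-count distribution and GOF against equal proportions -----------
  k <- dataset$task$n_cues_max
  cue_tab <- lapply(c(CONDITIONS, "overall"), function(cc) {
    nc <- if (cc == "overall") main_trials$n_cues else
      main_trials$n_cues[main_trials$condition == cc]
    counts <- tabulate(nc, nbins = k)
    g <- chisq_gof(counts, rep(1 / k, k))
    data.frame(condition = cc, t(counts / sum(counts)), chi2 = g$chi2,
               df = g$df, p = g$p, n = sum(counts))
  })
  cue_distribution <- do.call(rbind, cue_tab)
  names(cue_distribution)[2:(k + 1)] <- paste0("p", seq_len(k))

  # --- participant-level zero-order correlations --------------------------
  say("correlations")
  agg <- function(v, by) tapply(v, by, mean, na.rm = TRUE)
  p_cues <- agg(mets$deltas$n_cues, mets$deltas$participant)
  correlations <- list()
  if ("bcpd" %in% measures) {
    p_dbcpd <- agg(mets$deltas$d_bcpd, mets$deltas$participant)
    correlations$d_bcpd_vs_cues <- pearson_with_t(p_cues, p_dbcpd[names(p_cues)])
  }
  if ("ms_rate" %in% measures) {
    p_rate <- agg(mets$metrics$ms_rate, mets$metrics$participant)
    correlations$ms_rate_vs_cues <- pearson_with_t(p_cues, p_rate[names(p_cues)])
  }

  # --- main sequence -------------------------------------------------------
  main_sequence <- NULL
  if (!is.null(mets$events) && nrow(mets$events) >= 2) {
    say("main sequence on %d events", nrow(mets$events))
    main_sequence <- fit_main_sequence(mets$events)
  }

  # --- nested LMMs ---------------------------------------------------------
  lmms <- list()
  fit_quiet <- function(rows, dv) tryCatch(fit_lmm(rows, dv),
                                           error = function(e) e)
  if ("bcpd" %in% measures) lmms$d_bcpd <- fit_quiet(mets$deltas, "d_bcpd")
  if ("lhipa" %in% measures) lmms$d_lhipa <- fit_quiet(mets$deltas, "d_lhipa")
  if ("ms_rate" %in% measures) {
    lmms$ms_rate <- if (ms_rate_dv == "delta") fit_quiet(mets$deltas, "d_ms_rate")
    else fit_quiet(mets$metrics, "ms_rate")
  }
  if ("ms_magnitude" %in% measures) {
    lmms$ms_magnitude <- if (ms_rate_dv == "delta")
      fit_quiet(mets$deltas, "d_ms_magnitude") else fit_quiet(mets$metrics, "ms_magnitude")
  }
  lmms <- Filter(function(z) inherits(z, "effort_lmm"), lmms)

  report <- structure(list(
    cue_distribution = cue_distribution,
    correlations = correlations,
    main_sequence = main_sequence,
    lmms = lmms,
    metrics = mets$metrics,
    deltas = mets$deltas,
    events = mets$events,
    baselines = mets$baselines,
    n_participants = length(unique(dataset$trials$participant)),
    n_trials = nrow(main_trials),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "effort_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.effort_report <- function(x, ...) {
  cat(sprintf("<effort_report> %d participants, %d trials, %s detected events\n",
              x$n_participants, x$n_trials,
              if (is.null(x$events)) "no" else nrow(x$events)))
  if (!is.null(x$main_sequence)) print(x$main_sequence)
  for (nm in names(x$lmms)) {
    cat("\n"); print(x$lmms[[nm]])
  }
  invisible(x)
}

lmm_to_df <- function(l) {
  data.frame(dv = l$dv, l$fixed,
             lrt_chi2 = l$lrt_chi2, lrt_df = l$lrt_df, lrt_p = l$lrt_p,
             pseudo_r2_total = l$pseudo_r2_total,
             var_condition = l$varcomp[["condition"]],
             var_participant = l$varcomp[["participant"]],
             var_residual = l$varcomp[["residual"]],
             stringsAsFactors = FALSE)
}

#' Write a report bundle to disk
#'
#' Emits `cue_distribution.csv`, `correlations.csv`, `main_sequence.csv`,
#' one `lmm_<dv>.csv` per fitted model, the per-epoch metric and delta
#' tables, and a machine-readable `summary.json`.
#'
#' @param report an `effort_report`.
#' @param out_dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
  w(report$cue_distribution, "cue_distribution.csv")
  if (length(report$correlations)) {
    cors <- do.call(rbind, lapply(names(report$correlations), function(nm) {
      ct <- report$correlations[[nm]]
      data.frame(test = nm, r = ct$r, n = ct$n, df = ct$df, t = ct$t, p = ct$p)
    }))
    w(cors, "correlations.csv")
  }
  if (!is.null(report$main_sequence)) {
    ms <- report$main_sequence
    w(data.frame(slope = ms$slope, intercept = ms$intercept,
                 r_squared = ms$r_squared, n_events = ms$n_events,
                 slope_se = ms$slope_se, intercept_se = ms$intercept_se),
      "main_sequence.csv")
  }
  for (nm in names(report$lmms))
    w(lmm_to_df(report$lmms[[nm]]), paste0("lmm_", nm, ".csv"))
  w(report$metrics, "epoch_metrics.csv")
  w(report$deltas, "deltas.csv")
  summary_list <- list(
    n_participants = report$n_participants,
    n_trials = report$n_trials,
    n_events = if (is.null(report$events)) 0L else nrow(report$events),
    main_sequence = if (is.null(report$main_sequence)) NULL else
      report$main_sequence[c("slope", "intercept", "r_squared", "n_events")],
    correlations = lapply(report$correlations, function(ct)
      ct[c("r", "n", "df", "t", "p")]),
    lmms = lapply(report$lmms, function(l)
      list(fixed = l$fixed, lrt_chi2 = l$lrt_chi2, lrt_df = l$lrt_df,
           lrt_p = l$lrt_p, pseudo_r2_total = l$pseudo_r2_total,
           varcomp = as.list(l$varcomp))))
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a simulated dataset to disk
#'
#' Emits `samples.csv`, `trials.csv` and `truth.json` (ground-truth ledger).
#'
#' @param ds an `experiment_dataset` (with a `truth` element).
#' @param out_dir output directory.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_samples(ds$recordings, file.path(out_dir, "samples.csv"))
  write_trials(ds$trials, file.path(out_dir, "trials.csv"))
  if (!is.null(ds$truth))
    jsonlite::write_json(ds$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}
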