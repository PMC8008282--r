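test_that("cue-count sampling respects its distribution contract", {
  expect_identical(sample_cue_counts(0, overall_cue_probs()), integer(0))
  expect_identical(sample_cue_counts(10, c(1, 0, 0, 0, 0, 0)), rep(1L, 10))
  expect_error(sample_cue_counts(5, c(0.5, 0.4)), class = "oe_validation_error")

  set.seed(1)
  draws <- sample_cue_counts(1e5, overall_cue_probs())
  expect_true(all(draws >= 1 & draws <= 6))
  expect_lt(abs(mean(draws == 1) - 0.49), 0.01)
})

test_that("sampled cue counts pass goodness-of-fit against their law", {
  # chi-square GOF on the positive-probability bins at the experiment's
  # trial count; non-significant at alpha = 0.01 in at least 95/100 seeds
  probs <- overall_cue_probs()[1:5] / sum(overall_cue_probs()[1:5])
  ok <- 0L
  for (s in 1:100) {
    set.seed(s)
    draws <- sample_cue_counts(504, probs)
    g <- chisq_gof(tabulate(draws, 5), probs)
    if (g$p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("the same seed reproduces an identical dataset", {
  cfg <- small_config(seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$trials, d2$trials)
  expect_identical(d1$truth, d2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_samples(d1$recordings, f1)
  write_samples(d2$recordings, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("the default design yields 21 participants and 504 main trials", {
  ds <- cached_dataset()
  expect_identical(length(unique(ds$trials$participant)), 21L)
  expect_identical(sum(!ds$trials$is_training), 504L)
  expect_identical(sum(ds$trials$is_training), 63L)
  cond_n <- table(ds$truth$participants$condition)
  expect_identical(as.integer(cond_n[c("neutral", "aversive", "erotic")]),
                   c(8L, 7L, 6L))
  expect_identical(nrow(validate_dataset(ds)), 0L)
})

test_that("a single-cue trial carries exactly one epoch of the fixed cue duration", {
  cfg <- small_config(seed = 3)
  sim <- simulate_trial("P01", 1, "neutral", 1, cfg, 4000)
  ep <- trial_epochs(sim$trial)
  expect_identical(nrow(ep), 1L)
  expect_equal(ep$offset_ms - ep$onset_ms, 2000)
})

test_that("zeroed effect slopes give constant latent epoch means and a silent trace", {
  eff <- effect_params(bcpd_slope_per_cue = c(neutral = 0, aversive = 0, erotic = 0),
                       ms_rate_slope_per_cue = c(neutral = 0, aversive = 0, erotic = 0),
                       pupil_hf_sd_per_cue = 0)
  cfg <- small_config(seed = 11, effects = eff)
  sim <- simulate_trial("P01", 1, "aversive", 5, cfg, 4000)
  expect_equal(diff(range(sim$truth$epochs$latent_pupil_mean)), 0)
  expect_equal(diff(range(sim$truth$epochs$ms_rate)), 0)
})

test_that("a trial with no events and no blinks detects as empty", {
  eff <- effect_params(blink_rate_per_s = 1e-9)
  # the rate floor keeps expected rates positive; a 2 s single-cue trial at
  # the floor (0.05 events/s) is almost always event-free, so draw until so
  cfg <- simulation_config(task = task_spec(), effects = eff, seed = 1)
  set.seed(2)
  found <- FALSE
  for (i in 1:20) {
    eff0 <- effect_params(ms_rate_base = 0.05,
                          ms_rate_slope_per_cue = c(neutral = 0, aversive = 0, erotic = 0),
                          blink_rate_per_s = 1e-9)
    cfg0 <- simulation_config(task = task_spec(), effects = eff0, seed = 1)
    sim <- simulate_trial("P01", i, "neutral", 1, cfg0, 4000)
    if (nrow(sim$truth$events) == 0) { found <- TRUE; break }
  }
  expect_true(found)
  pre <- preprocess_recording(sim$recording, cfg$geometry)
  ev <- detect_trial_microsaccades(pre)
  expect_identical(nrow(ev), 0L)
})

test_that("injected events follow the configured main sequence", {
  # regressing the injected (waveform-encoded) peak velocity on injected
  # magnitude recovers the generator slope within 2%
  set.seed(99)
  eff <- effect_params()
  A <- oculoeffort:::draw_magnitudes(5000, eff)
  v <- eff$main_seq_slope * A + eff$main_seq_intercept +
    rnorm(5000, 0, eff$main_seq_noise_sd)
  v <- pmax(v, 165 * A + 2)
  enc <- vapply(seq_along(A), function(i)
    oculoeffort:::ms_waveform(A[i], v[i])$peak_velocity, numeric(1))
  fit <- fit_main_sequence(data.frame(magnitude_deg = A, peak_velocity_dps = enc))
  expect_lt(abs(fit$slope - eff$main_seq_slope) / eff$main_seq_slope, 0.02)
})

test_that("at least 90% of injected events are recovered within 10 ms", {
  ds <- cached_dataset()
  rep <- cached_report()
  truth <- ds$truth$events
  main_keys <- oculoeffort:::key_pt(ds$trials$participant[!ds$trials$is_training],
                                    ds$trials$trial[!ds$trials$is_training])
  truth <- truth[oculoeffort:::key_pt(truth$participant, truth$trial) %in% main_keys, ]
  truth <- truth[truth$magnitude_deg >= 0.1, ]
  hit <- 0L
  for (k in unique(oculoeffort:::key_pt(truth$participant, truth$trial))) {
    ti <- truth[oculoeffort:::key_pt(truth$participant, truth$trial) == k, ]
    ei <- rep$events[oculoeffort:::key_pt(rep$events$participant, rep$events$trial) == k, ]
    hit <- hit + sum(vapply(ti$onset_ms, function(o)
      nrow(ei) > 0 && any(abs(ei$onset_ms - o) <= 10), logical(1)))
  }
  expect_gte(hit / nrow(truth), 0.90)
})

test_that("detected microsaccade rates track generator rates per condition and cue", {
  # mean detected rate per condition x cue cell across seeds, within 15% of
  # the generator rate; restricted to cells with enough expected events for
  # the comparison to be informative
  eff <- effect_params()
  sums <- list()
  for (s in 1:10) {
    ds <- if (s == 1) cached_dataset() else generate_dataset(simulation_config(seed = 42 + s))
    mets <- compute_dataset_metrics(ds, measures = "ms_rate")$metrics
    sums[[s]] <- aggregate(list(rate = mets$ms_rate),
                           by = mets[c("condition", "epoch_index")],
                           mean, na.rm = TRUE)
  }
  all <- do.call(rbind, sums)
  cell <- aggregate(list(rate = all$rate), by = all[c("condition", "epoch_index")], mean)
  n_cell <- aggregate(list(n = all$rate), by = all[c("condition", "epoch_index")], length)
  for (i in seq_len(nrow(cell))) {
    nom <- ms_rate_for_cue(eff, cell$condition[i], cell$epoch_index[i])
    if (nom < 0.3) next
    # expected events per cell per seed: trials * P(cue count >= k) * dur * rate
    p_ge <- sum(eff$cue_count_probs[cell$condition[i], cell$epoch_index[i]:6])
    expected <- 24 * 7 * p_ge * 1.7 * nom * 10
    if (expected < 150) next
    expect_lt(abs(cell$rate[i] / nom - 1), 0.15,
              label = sprintf("relative rate error, %s cue %d",
                              cell$condition[i], cell$epoch_index[i]))
  }
})
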