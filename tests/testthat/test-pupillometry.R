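# Frozen reference: a 64-sample standard-normal signal and its periodized
# sym16 detail coefficients at levels 1 and 2, computed with an independent
# wavelet implementation (PyWavelets downcoef, mode "per").
sig <- c(
  0.30471707975443135, -1.0399841062404955, 0.7504511958064572,
  0.9405647163912139, -1.9510351886538364, -1.302179506862318,
  0.12784040316728537, -0.3162425923435822, -0.016801157504288795,
  -0.85304392757358, 0.8793979748628286, 0.7777919354289483,
  0.06603069756121605, 1.1272412069680329, 0.4675093422520456,
  -0.8592924628832382, 0.36875078408249884, -0.9588826008289989,
  0.8784503013072725, -0.049925910986252896, -0.18486236354526056,
  -0.6809295444039414, 1.2225413386740303, -0.15452948206880215,
  -0.4283278221631072, -0.3521335504882296, 0.5323091855533487,
  0.36544406436407834, 0.4127326115959884, 0.43082100300788273,
  2.1416476008704612, -0.4064150163846156, -0.5122427290715373,
  -0.8137727282478777, 0.6159794225754956, 1.1289722927208916,
  -0.11394745765487507, -0.840156476962528, -0.8244812156912396,
  0.6505927878247011, 0.7432541712034423, 0.543154268305195,
  -0.6655097072886943, 0.23216132306671977, 0.11668580914072822,
  0.21868859672901295, 0.8714287779481898, 0.22359554877468227,
  0.6789135630718949, 0.06757906948889146, 0.28911939868998415,
  0.6312882258385404, -1.4571558198556664, -0.31967121635730134,
  -0.4703726542927955, -0.6388778482433419, -0.27514225122668373,
  1.4949413112343959, -0.8658311156932432, 0.9682783545914808,
  -1.6828697716158048, -0.33488502998577485, 0.1627530651050056,
  0.5862223313592781)

d1_ref <- c(
  -1.7068777665367383, 1.5353783793760538, -0.39440560483835985,
  -0.0879798949991698, -1.1416408963365288, 0.26251410888007687,
  0.5922401181235558, -0.7553039621071228, -1.3817049612363135,
  -0.017765809201081895, -1.0746892260382483, -0.23847457869039956,
  -0.41187234044496485, 0.2291439872450597, -0.9766875897518552,
  -0.7201312535438451, -0.5683409269352914, 0.4850993299182556,
  -0.047960233889551014, 0.41658261079530284, 0.2438238648293761,
  0.5812922701299769, -0.3320836559369231, -0.3252062342641698,
  -0.5440418480729659, 1.0276537795357104, 0.6119181964485368,
  -0.2841072417725434, 1.272338095907142, 1.8768982295649677,
  0.1804223976256989, 0.4809139384735791)

d2_ref <- c(
  0.8791090263479716, 0.36088628625439684, -0.16730033503254652,
  0.2361785024345102, 0.7823993146989402, 1.0518616821561733,
  0.04611362792874769, 1.364472712734763, 1.1309580259691965,
  -1.5347471183867525, -0.8309925349633429, 0.10722188042381577,
  0.7969371651074334, -0.5280291518638688, 1.0815680885873413,
  0.5679731750134202)

test_that("the periodized DWT reproduces independent reference coefficients", {
  expect_equal(oculoeffort:::dwt_detail(sig, 1L), d1_ref, tolerance = 1e-12)
  expect_equal(oculoeffort:::dwt_detail(sig, 2L), d2_ref, tolerance = 1e-12)
  expect_identical(oculoeffort:::dwt_max_level(2000), 6L)
  expect_identical(oculoeffort:::dwt_max_level(1500), 5L)
  # odd lengths are handled by repeating the last sample
  expect_length(oculoeffort:::dwt_detail(sig[1:63], 1L), 32L)
})

test_that("baselines pool smoothed training pupil across trials", {
  r1 <- flat_recording(2000, pupil = 4000)
  b <- compute_baseline(list(r1))
  expect_equal(b$baseline_value, 4000)
  expect_identical(b$n_samples_used, 2000L)

  r2 <- flat_recording(2000, pupil = 3900, trial = 2L)
  r3 <- flat_recording(2000, pupil = 4100, trial = 3L)
  expect_equal(compute_baseline(list(r2, r3))$baseline_value, 4000)

  expect_error(compute_baseline(list(flat_recording(50))),
               class = "oe_insufficient_data")
  expect_error(compute_baseline(list()), class = "oe_insufficient_data")
})

test_that("a noise-free generator baseline is recovered from training trials", {
  eff <- effect_params(hippus_amp = 0, pupil_hf_sd_base = 0,
                       pupil_hf_sd_per_cue = 0, blink_rate_per_s = 1e-9)
  cfg <- small_config(seed = 31, effects = eff)
  recs <- lapply(1:3, function(j)
    simulate_trial("P01", j, "neutral", 1, cfg, 4123.4, is_training = TRUE)$recording)
  b <- compute_baseline(recs)
  expect_equal(b$baseline_value, 4123.4, tolerance = 0.2)
})

test_that("BCPD is the epoch mean minus baseline, linear in shifts", {
  base <- list(baseline_value = 4000)
  class(base) <- "pupil_baseline"
  expect_equal(bcpd(rep(4000, 500), base), 0)
  expect_equal(bcpd(rep(4100, 500), base), 100)

  set.seed(14)
  slice <- rnorm(500, 4050, 20)
  b0 <- bcpd(slice, 4000)
  expect_equal(bcpd(slice + 37, 4000), b0 + 37)      # additive in the epoch
  expect_equal(bcpd(slice + 37, 4037), b0)           # baseline shift cancels
  expect_warning(v <- bcpd(rnorm(50), 4000), "fewer than")
  expect_true(is.na(v))
})

test_that("generator latent means encode the condition-specific dilation slopes", {
  ds <- cached_dataset()
  ep <- merge(ds$truth$epochs,
              ds$truth$participants[c("participant", "condition")])
  ep <- ep[!ep$is_training, ]
  neu5 <- ep[ep$condition == "neutral" & ep$epoch_index == 5, ][1, ]
  neu1 <- ep[ep$condition == "neutral" & ep$participant == neu5$participant &
               ep$trial == neu5$trial & ep$epoch_index == 1, ]
  # latent BCPD difference between cue 5 and cue 1 is exactly 4 * 37
  expect_equal(neu5$latent_pupil_mean - neu1$latent_pupil_mean, 148)
})

test_that("LHIPA normalises by duration and is invariant to amplitude scaling", {
  set.seed(15)
  n <- 1024
  p <- 4000 + 30 * sin(2 * pi * 0.2 * (0:(n - 1)) / 1000) + rnorm(n, 0, 40)
  v1 <- lhipa(p, dt = 1e-3)
  # same samples at half the sampling interval: half the duration, same
  # coefficient structure, so the index exactly doubles
  expect_equal(lhipa(p, dt = 5e-4), 2 * v1)
  # doubling amplitude rescales coefficients and threshold together
  expect_equal(lhipa(2 * p, dt = 1e-3), v1)
})

test_that("LHIPA handles degenerate and gappy slices explicitly", {
  expect_equal(suppressWarnings(lhipa(rep(4000, 1024))), 0)
  expect_error(lhipa(rnorm(100, 4000)), class = "oe_insufficient_data")
  p <- rnorm(1024, 4000, 30)
  p[1:400] <- NA
  expect_warning(v <- lhipa(p), "missing")
  expect_true(is.na(v))
  p2 <- rnorm(1024, 4000, 30)
  p2[sample(1024, 80)] <- NA
  expect_false(is.na(lhipa(p2)))
  expect_warning(va <- lhipa(rep(NA_real_, 1024)), "missing")
  expect_true(is.na(va))
})
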