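test_that("blink detection pads and merges missing-pupil runs", {
  rec <- flat_recording(300)
  expect_identical(nrow(detect_blinks(rec)), 0L)

  rec$pl[101:151] <- NA  # 100-150 ms
  b <- detect_blinks(rec, pad_ms = 50)
  expect_identical(nrow(b), 1L)
  expect_equal(b$onset_ms, 50)
  expect_equal(b$offset_ms, 200)
  expect_identical(b$eye, "left")

  # two runs 2 ms apart pad 50 -> single merged interval; oracle by direct
  # marking of padded samples
  rec2 <- flat_recording(400)
  rec2$pl[101:120] <- NA
  rec2$pr[123:140] <- NA
  b2 <- detect_blinks(rec2, pad_ms = 50)
  expect_identical(nrow(b2), 1L)
  marked <- rep(FALSE, 400)
  for (i in which(is.na(rec2$pl) | is.na(rec2$pr)))
    marked[max(1, i - 50):min(400, i + 50)] <- TRUE
  runs <- oculoeffort:::true_runs(marked)
  expect_identical(nrow(runs), 1L)
  expect_equal(b2$onset_ms, rec2$t[runs[1, "start"]])
  expect_equal(b2$offset_ms, rec2$t[runs[1, "end"]])
})

test_that("blink masking is complete, counted and idempotent", {
  rec <- flat_recording(500)
  expect_identical(mask_blinks(rec, detect_blinks(rec)), rec)

  rec$pl[200:260] <- NA
  b <- detect_blinks(rec, pad_ms = 40)
  m1 <- mask_blinks(rec, b)
  expect_identical(length(m1$t), length(rec$t))
  # masked fraction equals summed padded blink length over the span
  expect_identical(sum(is.na(m1$xl)), sum(rec$t >= b$onset_ms & rec$t <= b$offset_ms))
  expect_identical(mask_blinks(m1, b), m1)

  full <- data.frame(onset_ms = 0, offset_ms = 499, eye = "both")
  expect_true(all(is.na(mask_blinks(rec, full)$pr)))
})

test_that("binocular averaging uses the mean with single-eye fallback", {
  rec <- gaze_recording("P", 1, 0:2,
                        xl = c(100, NA, NA), yl = c(10, 20, NA),
                        xr = c(110, 110, NA), yr = c(10, NA, NA),
                        pl = c(4000, 4000, 4000), pr = c(4100, 4100, 4100))
  cyc <- average_eyes(rec)
  expect_equal(cyc$x, c(105, 110, NA))
  expect_equal(cyc$y, c(10, 20, NA))
  expect_equal(cyc$p, rep(4050, 3))
})

test_that("averaging is symmetric under swapping the eyes", {
  set.seed(4)
  n <- 200
  mk <- function() {
    xl <- rnorm(n, 512); xr <- rnorm(n, 512)
    yl <- rnorm(n, 384); yr <- rnorm(n, 384)
    pl <- runif(n, 3900, 4100); pr <- runif(n, 3900, 4100)
    xl[sample(n, 20)] <- NA; pr[sample(n, 10)] <- NA
    a <- gaze_recording("P", 1, 0:(n - 1), xl, yl, xr, yr, pl, pr)
    b <- gaze_recording("P", 1, 0:(n - 1), xr, yr, xl, yl, pr, pl)
    list(a = average_eyes(a), b = average_eyes(b))
  }
  two <- mk()
  expect_equal(two$a, two$b)
})

test_that("pixel-to-degree conversion is centred, calibrated and monotone", {
  g <- default_geometry()
  expect_equal(pixels_to_degrees(g$screen_width_px / 2, g, "x"), 0)
  expect_equal(pixels_to_degrees(g$screen_height_px / 2, g, "y"), 0)
  # 1 cm off-centre at 57 cm is atan(1/57) = 1.00509 degrees
  px_per_cm <- g$screen_width_px / g$screen_width_cm
  one_cm <- pixels_to_degrees(g$screen_width_px / 2 + px_per_cm, g, "x")
  expect_equal(one_cm, atan(1 / 57) * 180 / pi, tolerance = 1e-9)
  expect_equal(one_cm, 1.00509, tolerance = 1e-5)
  offs <- seq(0, 400, by = 25)
  degs <- pixels_to_degrees(g$screen_width_px / 2 + offs, g, "x")
  expect_true(all(diff(degs) > 0))
  # inverse round trip
  expect_equal(degrees_to_pixels(degs, g, "x"), g$screen_width_px / 2 + offs,
               tolerance = 1e-9)
})

test_that("pupil smoothing is averaging with missing-aware windows", {
  expect_equal(smooth_pupil(rep(4000, 200), 100), rep(4000, 200))

  # single impulse of height h spreads into a plateau of height h / w
  w <- 25
  x <- rep(0, 200); x[100] <- 50
  sm <- smooth_pupil(x, window_ms = w, dt_ms = 1)
  expect_equal(max(sm), 50 / w)
  expect_identical(sum(sm > 0), as.integer(w))

  set.seed(2)
  z <- rnorm(500, 4000, 50)
  expect_lt(var(smooth_pupil(z, 100), na.rm = TRUE), var(z))

  z[200:220] <- NA
  smz <- smooth_pupil(z, 100)
  expect_false(any(is.na(smz)))      # gaps shorter than the window are bridged
  expect_true(all(is.na(smooth_pupil(rep(NA_real_, 50), 10))))
})

test_that("I-DT finds single fixations, splits distant clusters, skips gaps", {
  cfg <- preprocess_config()
  t <- 0:2999
  fx <- detect_fixations(t, rep(0.1, 3000), rep(-0.2, 3000), cfg)
  expect_identical(nrow(fx), 1L)
  expect_equal(fx$onset_ms, 0)
  expect_equal(fx$offset_ms, 2999)

  # two stationary clusters 5 degrees apart with a 40 ms transition
  x <- c(rep(0, 1000), seq(0, 5, length.out = 40), rep(5, 1000))
  y <- rep(0, length(x))
  fx2 <- detect_fixations(seq_along(x) - 1, x, y, cfg)
  expect_identical(nrow(fx2), 2L)
  expect_lt(fx2$offset_ms[1], 1040)
  expect_gt(fx2$onset_ms[2], 999)

  expect_identical(nrow(detect_fixations(t, rep(NA_real_, 3000),
                                         rep(NA_real_, 3000), cfg)), 0L)
})

test_that("I-DT matches the exhaustive window-scan oracle", {
  cfg <- preprocess_config()
  set.seed(10)
  for (case in 1:5) {
    n <- sample(500:2000, 1)
    tr <- drift_trace(n, step_sd = 0.004)
    # occasional displacement jumps and a missing gap
    for (j in sample(100:(n - 120), 3)) {
      shift <- runif(1, 0.3, 3)
      tr$x[j:n] <- tr$x[j:n] + shift * sample(c(-1, 1), 1)
    }
    if (case %% 2 == 0) tr$x[300:360] <- NA
    t <- seq_len(n) - 1
    mine <- detect_fixations(t, tr$x, tr$y, cfg)
    oracle <- idt_oracle(t, tr$x, tr$y, cfg)
    expect_identical(mine$start_idx, oracle$start_idx)
    expect_identical(mine$end_idx, oracle$end_idx)
  }
})

test_that("fixations avoid blinks and never exceed the trace duration", {
  ds <- cached_dataset()
  rec <- ds$recordings[[oculoeffort:::key_pt("P01", 4)]]
  pre <- preprocess_recording(rec, ds$geometry)
  if (nrow(pre$fixations) && nrow(pre$blinks)) {
    for (i in seq_len(nrow(pre$blinks)))
      expect_false(any(pre$fixations$onset_ms <= pre$blinks$offset_ms[i] &
                         pre$fixations$offset_ms >= pre$blinks$onset_ms[i]))
  }
  expect_lte(sum(pre$fixations$offset_ms - pre$fixations$onset_ms),
             max(pre$t) - min(pre$t))
})
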