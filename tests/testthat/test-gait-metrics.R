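# gait metric kernels and per-subject aggregation

test_that("step interval kernels match their closed forms", {
  expect_identical(step_times(c(0, 1, 2)), c(1, 1))
  expect_warning(st <- step_times(1), "fewer than 2")
  expect_length(st, 0)

  iv <- c(1, 1, 1)
  expect_identical(mean_step_time(iv), 1)
  expect_identical(step_time_cv(iv), 0)
  expect_identical(step_regularity(iv), 1e6)      # capped
  expect_identical(step_symmetry(iv), 1)

  iv <- c(0.9, 1.1)
  expect_equal(mean_step_time(iv), 1)
  expect_equal(step_time_cv(iv), 0.1)
  expect_equal(step_regularity(iv), 10)

  expect_equal(step_symmetry(c(1.0, 1.2)), 1 - 0.2 / 1.1)

  set.seed(2)
  iv <- runif(100, 0.5, 1.5)
  expect_equal(step_time_cv(iv),
               sqrt(mean((iv - mean(iv))^2)) / mean(iv), tolerance = 1e-12)
  expect_error(step_time_cv(c(-1, 1)), "zero mean")
})

test_that("symmetry decreases monotonically with generated asymmetry", {
  sym <- vapply(c(0, 0.05, 0.1, 0.2), function(a) {
    x <- generate_accel_stream(
      gait_profile(step_time_cv = 0, asymmetry = a, noise_sd = 0,
                   bout_count = 1, bout_steps = 60), fs = 50, seed = 1)
    iv <- diff(attr(x, "truth")$bouts[[1]]$step_times)
    step_symmetry(iv)
  }, numeric(1))
  expect_true(all(diff(sym) < 0))
})

test_that("stride regularity: periodic, noise, and cv monotonicity", {
  fs <- 50
  tt <- seq(0, 40, by = 1 / fs)
  x <- sin(2 * pi * tt / 1.46) + 0.5 * sin(2 * pi * tt / 0.73)
  expect_gt(stride_regularity(x, fs, 0.73), 0.99)
  set.seed(3)
  wn <- vapply(1:50, function(i)
    stride_regularity(rnorm(2000), fs, 0.73), numeric(1))
  expect_lt(abs(mean(wn)), 0.05)
  expect_true(is.na(stride_regularity(rep(1, 1000), fs, 0.73)))
  sr <- vapply(c(0.01, 0.05, 0.1), function(cv) {
    a <- generate_accel_stream(
      gait_profile(step_time_cv = cv, asymmetry = 0, noise_sd = 0.05,
                   bout_count = 1, bout_steps = 100), fs = 50, seed = 4)
    b <- attr(a, "truth")$bouts[[1]]
    filt <- bandpass(a$vt, fs = 50)
    stride_regularity(filt[b$start:b$end], 50, 0.73)
  }, numeric(1))
  expect_true(all(diff(sr) < 0))
})

test_that("walking speed uses the 0.7 m constant step length", {
  expect_equal(walking_speed(100, 70), 1.0)
  expect_identical(walking_speed(0, 0), 0)
  expect_error(walking_speed(10, 0), "positive")
  # cadence 1/0.73 -> 0.7/0.73 m/s
  expect_equal(walking_speed(200, 200 * 0.73), 0.7 / 0.73)
})

test_that("rms closed forms", {
  tt <- seq(0, 100, by = 0.01)
  expect_equal(rms(sin(2 * pi * tt)), 1 / sqrt(2), tolerance = 1e-3)
  expect_identical(rms(rep(0, 5)), 0)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
})

test_that("harmonic ratio: pure tones and a constructed 4:1 mixture", {
  fs <- 50; stride <- 0.5                       # stride frequency, Hz
  tt <- seq(0, 60, by = 1 / fs)
  even_tone <- sin(2 * pi * 2 * stride * tt)
  hr <- harmonic_ratio(even_tone, fs, stride)
  expect_true(attr(hr, "capped") || as.numeric(hr) > 100)
  odd_tone <- sin(2 * pi * stride * tt)
  expect_lt(as.numeric(harmonic_ratio(odd_tone, fs, stride)), 0.05)
  mix <- 2 * sin(2 * pi * 2 * stride * tt) + 1 * sin(2 * pi * stride * tt)
  expect_lt(abs(as.numeric(harmonic_ratio(mix, fs, stride)) - 4) / 4, 0.1)
  # invariant to amplitude scaling
  expect_equal(as.numeric(harmonic_ratio(5 * mix, fs, stride)),
               as.numeric(harmonic_ratio(mix, fs, stride)), tolerance = 1e-9)
})

test_that("entropy: constant, uniform occupancy, oracle equivalence", {
  expect_identical(entropy(rep(2.5, 100)), 0)
  x <- rep(seq(0, 1, length.out = 8), each = 10) +
    rep(seq(0, 0.9, length.out = 10) / 80, times = 8)
  expect_equal(entropy(x, n_bins = 8), log(8), tolerance = 1e-9)
  set.seed(5)
  g <- rnorm(5000)
  expect_equal(entropy(g, 32), loop_entropy(g, 32), tolerance = 1e-12)
  # affine rescaling leaves the histogram shape unchanged
  expect_equal(entropy(3 * g + 7, 32), entropy(g, 32), tolerance = 1e-12)
})

test_that("per-subject aggregation sums steps and averages metrics", {
  a <- generate_accel_stream(gait_profile(bout_count = 1), fs = 50, seed = 6)
  filt <- bandpass(a$vt, fs = 50)
  pk <- detect_peaks(filt, 50, 0.5)
  b1 <- segment_bouts(pk, 50)
  one <- compute_gait_features(a, b1)
  expect_identical(names(one), gait_feature_names())
  # duplicated identical bout: metrics unchanged, steps doubled
  two <- compute_gait_features(a, c(b1, b1))
  expect_identical(two$n_steps, 2L * one$n_steps)
  expect_equal(two$mean_step_time_s, one$mean_step_time_s)
  expect_equal(two$hr_vt, one$hr_vt)
  expect_equal(two$walking_speed_mps, one$walking_speed_mps)
  # no bouts: all-missing row with zero steps
  none <- compute_gait_features(a, list())
  expect_identical(none$n_steps, 0L)
  expect_true(is.na(none$mean_step_time_s))
})

test_that("subject-level mean step time tracks the generator truth", {
  for (s in 1:4) {
    p <- gait_profile(mean_step_time = 0.9, bout_count = 2)
    a <- generate_accel_stream(p, fs = 50, seed = s)
    tru <- unlist(lapply(attr(a, "truth")$bouts,
                         function(b) diff(b$step_times)))
    g <- extract_gait_features(a, NULL)
    expect_lt(abs(g$mean_step_time_s - mean(tru)) / mean(tru), 0.02)
  }
})
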