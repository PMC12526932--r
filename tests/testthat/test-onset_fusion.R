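test_that("magnitude is the per-sample Euclidean norm", {
  tr <- list(acc_x = c(3, 0, 1), acc_y = c(4, 0, 1), acc_z = c(0, 0, 1))
  expect_equal(magnitude(tr), c(5, 0, sqrt(3)))
  expect_equal(magnitude(tr)[3], 1.7320508, tolerance = 1e-7)
  expect_error(magnitude(list(acc_x = numeric(0), acc_y = numeric(0),
                              acc_z = numeric(0))), "empty")
  expect_error(magnitude(list(acc_x = 1:3, acc_y = 1:2, acc_z = 1:3)),
               "equal length")
})

test_that("the EWMA recursion matches its defining examples", {
  # hand-unrolled recursion
  expect_equal(ewma_envelope(c(0, 1, 1, 3), alpha = 0.5)$y,
               c(0, 0.5, 0.25, 1.125))
  # constant input: zero envelope
  expect_equal(ewma_envelope(rep(2.5, 50), alpha = 0.3)$y, rep(0, 50))
  # alpha = 0 collapses to |x[n-1] - x[n]|
  x <- c(1, 4, 2, 2, 7)
  expect_equal(ewma_envelope(x, alpha = 0)$y, c(0, abs(diff(x))))
  # parameter validation
  expect_error(ewma_envelope(x, alpha = 1), "alpha")
  expect_error(ewma_envelope(x, alpha = -0.1), "alpha")
  expect_error(ewma_envelope(3, alpha = 0.5), "length")
})

test_that("the EWMA filter matches a naive loop oracle on random inputs", {
  for (seed in 1:10) {
    x <- withr::with_seed(seed, stats::rnorm(500))
    alpha <- withr::with_seed(seed + 100, stats::runif(1, 0, 0.99))
    expect_equal(ewma_envelope(x, alpha = alpha)$y, naive_ewma(x, alpha),
                 tolerance = 1e-12)
  }
})

test_that("envelopes are non-negative and length-preserving", {
  x <- withr::with_seed(5, stats::rnorm(200, 9.81, 0.3))
  env <- ewma_envelope(x, alpha = 0.7)
  expect_length(env$y, length(x))
  expect_true(all(env$y >= 0))
})

test_that("peak detection reports threshold up-crossings with refractoriness", {
  params <- fusion_params(threshold = 1, refractory_ms = 50)

  # envelope everywhere below threshold: no peaks
  env_low <- structure(list(t = (0:99) * 2, x = rep(0, 100),
                            y = rep(0.5, 100)), class = "ewma_envelope")
  expect_length(detect_peaks(env_low, params), 0L)

  # single isolated transient: one peak at the crossing sample
  y <- rep(0, 100); y[40:42] <- c(2, 3, 1.5)
  env1 <- structure(list(t = (0:99) * 2, x = rep(0, 100), y = y),
                    class = "ewma_envelope")
  expect_equal(detect_peaks(env1, params), 39 * 2)

  # two transients 10 ms apart with a 50 ms refractory: one peak
  y2 <- rep(0, 100); y2[40] <- 2; y2[45] <- 2  # samples 10 ms apart at 500 Hz
  env2 <- structure(list(t = (0:99) * 2, x = rep(0, 100), y = y2),
                    class = "ewma_envelope")
  expect_equal(detect_peaks(env2, params), 39 * 2)

  # beyond the refractory the second transient is reported again
  y3 <- rep(0, 100); y3[10] <- 2; y3[40] <- 2  # 60 ms apart
  env3 <- structure(list(t = (0:99) * 2, x = rep(0, 100), y = y3),
                    class = "ewma_envelope")
  expect_equal(detect_peaks(env3, params), c(9, 39) * 2)
})

test_that("raising the threshold never increases the number of peaks", {
  p <- device_profile("noisy", accel_noise_sd = 0.15)
  tr <- simulate_accel_trace(c(500, 1200, 1900), p, 3000, seed = 21)
  env <- ewma_envelope(magnitude(tr), alpha = 0.5, t = tr$t)
  # monotone once the threshold clears the noise floor (below it, sustained
  # supra-threshold noise merges crossings and the count is not meaningful)
  floor_y <- max(env$y[env$t < 450])
  thresholds <- seq(floor_y * 1.05, 4, length.out = 60)
  counts <- vapply(thresholds, function(th) {
    length(detect_peaks(env, fusion_params(threshold = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold calibration scales the baseline envelope noise", {
  p <- device_profile("noisy", accel_noise_sd = 0.1)
  tr <- simulate_accel_trace(2000, p, 3000, seed = 31)
  env <- ewma_envelope(magnitude(tr), alpha = 0.5, t = tr$t)
  th <- calibrate_threshold(env, baseline_ms = 1000, k = 8)
  expect_gt(th, 0)
  # the calibrated threshold separates noise from the tap: exactly one peak
  peaks <- detect_peaks(env, fusion_params(threshold = th))
  expect_length(peaks, 1L)
  expect_gte(peaks, 2000)
  expect_lte(peaks, 2002)
  # zero-variance baseline cannot be calibrated
  quiet <- ewma_envelope(rep(9.81, 100), alpha = 0.5, t = (0:99) * 2)
  expect_error(calibrate_threshold(quiet), "zero variance")
})

test_that("fusion picks the most recent in-window peak or falls back", {
  params <- fusion_params(threshold = 1, window_ms = 1000 / 120)
  logged <- 500

  # no peak in window: touchscreen fallback
  f0 <- fuse_rt(logged, peaks = c(100, 480), stimulus_time = 400,
                params = params)
  expect_equal(f0$rt_ms, 100)
  expect_equal(f0$source, "touchscreen")

  # one peak 3 ms before the logged touch
  f1 <- fuse_rt(logged, peaks = 497, stimulus_time = 400, params = params)
  expect_equal(f1$rt_ms, 97)
  expect_equal(f1$source, "accelerometer")

  # two in-window peaks: the most recent (latest) wins
  f2 <- fuse_rt(logged, peaks = c(493, 498), stimulus_time = 400,
                params = params)
  expect_equal(f2$response_time_ms, 498)

  # ordering contract
  expect_error(fuse_rt(logged, peaks = 497, stimulus_time = 600,
                       params = params), "precede")
})

test_that("fused RT never exceeds the touchscreen-only RT", {
  p <- noiseless_profile()
  params <- fusion_params(threshold = 1, window_ms = touch_frame_ms(p))
  taps <- 200 * (1:100) + withr::with_seed(41, stats::runif(100, 0, 150))
  tr <- simulate_accel_trace(taps, p, duration_ms = 20400, seed = 1)
  peaks <- detect_taps(tr, params)
  touches <- simulate_touch_events(taps, p, seed = 2)
  for (i in seq_along(taps)) {
    fused <- fuse_rt(touches$logged_time_ms[i], peaks, stimulus_time = 0,
                     params = params)
    expect_lte(fused$rt_ms, touches$logged_time_ms[i])
  }
})

test_that("fusion recovers tap times at accelerometer resolution", {
  # noiseless 500 Hz accelerometer vs 120 Hz touchscreen, jittered taps
  p <- noiseless_profile()
  params <- fusion_params(threshold = 1, window_ms = touch_frame_ms(p))
  # taps jittered over 20 accelerometer periods (and ~4.8 touch frames),
  # spaced >= 60 ms so no tap falls inside the detector's refractory period
  n <- 1000
  taps <- 100 * (seq_len(n) - 1) + withr::with_seed(43, stats::runif(n, 0, 40))
  tr <- simulate_accel_trace(taps, p, duration_ms = 100 * n, seed = 1)
  peaks <- detect_taps(tr, params)
  touches <- simulate_touch_events(taps, p, seed = 2)
  fused_err <- touch_err <- numeric(n)
  for (i in seq_len(n)) {
    fused <- fuse_rt(touches$logged_time_ms[i], peaks,
                     stimulus_time = 100 * (i - 1), params = params)
    fused_err[i] <- abs((100 * (i - 1) + fused$rt_ms) - taps[i])
    touch_err[i] <- abs(touches$logged_time_ms[i] - taps[i])
  }
  expect_lte(max(fused_err), 4)           # accelerometer-grade resolution
  expect_gt(max(touch_err), 4)            # touchscreen alone cannot do this
  expect_lte(max(touch_err), 1000 / 120 + 1e-6)
})
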