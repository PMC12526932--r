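# Synthetic sensor streams: accelerometer traces, frame-quantized touch
# events, and the fully simulated timing-validation bench.

#' Simulate a 3-axis accelerometer trace with tap transients
#'
#' Produces a uniformly sampled trace at the profile's accelerometer rate:
#' a constant gravity baseline (9.81 units on the z axis; orientation effects
#' are out of scope) plus independent Gaussian noise per axis, with a brief
#' transient injected at each tap.  The transient is a 3-sample triangular
#' pulse (`amplitude/2, amplitude, amplitude/2`) on the z axis beginning at
#' the first sample at-or-after the tap time -- the minimal shape that yields
#' one sharp successive-difference peak for the detector.
#'
#' @param tap_times_ms Numeric vector of true physical contact times, ms;
#'   each must lie in `[t0_ms, t0_ms + duration_ms)`.
#' @param profile A [device_profile()]; supplies `accel_rate_hz` and
#'   `accel_noise_sd`.
#' @param duration_ms Trace duration, ms (> 0).
#' @param tap_amplitude Peak transient amplitude, acceleration units.
#' @param seed Integer seed; identical inputs and seed give an identical
#'   trace.
#' @param t0_ms Time of the first sample, ms.  The sampling clock is free
#'   running, so for physically consistent multi-trace simulations `t0_ms`
#'   should be a multiple of the sample period.
#' @return An object of class `accel_trace`: list with `t`, `acc_x`,
#'   `acc_y`, `acc_z` (equal lengths), `true_tap_times_ms` and `rate_hz`.
#' @examples
#' p <- device_profile("bench", accel_rate_hz = 500, accel_noise_sd = 0)
#' tr <- simulate_accel_trace(1000, p, duration_ms = 2000, seed = 1)
#' length(tr$t)  # 1000 samples
#' @export
simulate_accel_trace <- function(tap_times_ms, profile, duration_ms,
                                 tap_amplitude = 8, seed = 1, t0_ms = 0) {
  stopifnot(inherits(profile, "device_profile"))
  assert_scalar_number(duration_ms, "duration_ms", lower = 0, strict_lower = TRUE)
  assert_scalar_number(tap_amplitude, "tap_amplitude", lower = 0)
  tap_times_ms <- as.numeric(tap_times_ms)
  if (any(tap_times_ms < t0_ms | tap_times_ms >= t0_ms + duration_ms))
    stop_input("all tap times must lie in [t0_ms, t0_ms + duration_ms)")

  dt <- 1000 / profile$accel_rate_hz
  n <- floor(duration_ms / dt + 1e-9)
  t <- t0_ms + (seq_len(n) - 1) * dt

  with_seed(seed, {
    noise_sd <- profile$accel_noise_sd
    acc_x <- stats::rnorm(n, 0, noise_sd)
    acc_y <- stats::rnorm(n, 0, noise_sd)
    acc_z <- 9.81 + stats::rnorm(n, 0, noise_sd)
    pulse <- tap_amplitude * c(0.5, 1, 0.5)
    for (u in tap_times_ms) {
      i <- ceiling((u - t0_ms) / dt - 1e-9) + 1  # first sample at-or-after u
      idx <- i + 0:2
      idx <- idx[idx <= n]
      acc_z[idx] <- acc_z[idx] + pulse[seq_along(idx)]
    }
    structure(
      list(t = t, acc_x = acc_x, acc_y = acc_y, acc_z = acc_z,
           true_tap_times_ms = sort(tap_times_ms),
           rate_hz = profile$accel_rate_hz),
      class = "accel_trace"
    )
  })
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples at %g Hz, t in [%.1f, %.1f] ms, %d tap(s)\n",
              length(x$t), x$rate_hz, x$t[1L], x$t[length(x$t)],
              length(x$true_tap_times_ms)))
  invisible(x)
}

#' @export
as.data.frame.accel_trace <- function(x, ...) {
  data.frame(t = x$t, acc_x = x$acc_x, acc_y = x$acc_y, acc_z = x$acc_z)
}

#' Simulate OS-logged touchscreen events
#'
#' Each physical contact acquires a pipeline latency draw (Gaussian,
#' truncated at zero) and is then rounded *up* to the next frame boundary of
#' the touchscreen scan grid -- a scan-based digitizer reports at the scan
#' following contact, never before it.  With zero pipeline latency the
#' logging error is therefore pure quantization, bounded by one frame period
#' (8.33 ms at 120 Hz).
#'
#' @param true_contact_times_ms Sorted numeric vector of physical contact
#'   times, ms.
#' @param profile A [device_profile()]; supplies `touch_rate_hz` and
#'   `touch_pipeline_latency_ms`.
#' @param seed Integer seed for the latency draws.
#' @return Data frame with one row per contact: `logged_time_ms`,
#'   `true_contact_ms`; always `logged_time_ms >= true_contact_ms`.
#' @export
simulate_touch_events <- function(true_contact_times_ms, profile, seed = 1) {
  stopifnot(inherits(profile, "device_profile"))
  u <- as.numeric(true_contact_times_ms)
  if (is.unsorted(u)) stop_input("contact times must be sorted ascending")
  frame <- 1000 / profile$touch_rate_hz
  lat <- profile$touch_pipeline_latency_ms
  with_seed(seed, {
    draws <- pmax(0, stats::rnorm(length(u), lat[1L], lat[2L]))
    arrived <- u + draws
    logged <- ceiling(arrived / frame - 1e-9) * frame
    data.frame(logged_time_ms = logged, true_contact_ms = u)
  })
}

#' Simulate a timing-validation bench session
#'
#' Emulates the hardware bench in software.  Per trial: the device issues an
#' audio command (`t0`) and, after a randomized inter-stimulus delay
#' `delta1` drawn from `isi_range_ms`, a vibration command (`t1`).  The
#' *external* (physically true) onsets `t0'`, `t1'` are the command times
#' plus per-trial device latency draws.  A virtual robotic finger taps the
#' screen a uniform `tap_delay_range_ms` draw after the external vibration
#' onset; the tap is sensed through a simulated accelerometer trace and a
#' frame-quantized touch event, and the internal response timestamp `t2` is
#' the fused-detector output ([detect_peaks()] + [fuse_rt()]).  `t2'` is the
#' true tap time.
#'
#' The paired intervals `(t1 - t0)` vs `(t1' - t0')` (stimulus-onset
#' synchronization, "AA'") and `(t2 - t1)` vs `(t2' - t1')` (reaction time,
#' "BB'") are what [bench_deltas()] compares.  Constant injected latencies
#' reappear as the means of the corresponding deltas; latency SDs reappear in
#' their spread.
#'
#' @param profile A [device_profile()].
#' @param n_trials Number of trials (>= 1).
#' @param isi_range_ms Length-2 range of the scheduled audio-to-vibration
#'   delay, ms.
#' @param tap_delay_range_ms Length-2 range of the robotic-tap delay after
#'   external vibration onset, ms.
#' @param seed Integer seed; the whole session is a pure function of
#'   arguments and seed.
#' @param params Optional [fusion_params()] for the internal detector.  By
#'   default `window_ms` is set to the profile's touch frame period and the
#'   threshold to `tap_amplitude/8 + 6 * accel_noise_sd`, comfortably between
#'   the envelope noise floor and the tap response.
#' @param tap_amplitude Transient amplitude for the simulated taps.
#' @return Object of class `bench_session`: data frame with columns `trial`,
#'   `t0`, `t1`, `t2`, `t0_ext`, `t1_ext`, `t2_ext`, `delta1_ms`, `source`
#'   (times in ms, stored to 0.001 ms).
#' @export
simulate_bench_session <- function(profile, n_trials = 1000,
                                   isi_range_ms = c(500, 1500),
                                   tap_delay_range_ms = c(1000, 2000),
                                   seed = 1, params = NULL,
                                   tap_amplitude = 8) {
  stopifnot(inherits(profile, "device_profile"))
  if (!is.numeric(n_trials) || n_trials < 1)
    stop_input("`n_trials` must be >= 1")
  n_trials <- as.integer(n_trials)
  check_range <- function(r, nm) {
    if (!is.numeric(r) || length(r) != 2L || r[1L] > r[2L] || r[1L] < 0)
      stop_input("`%s` must be a valid nonnegative (low, high) range", nm)
  }
  check_range(isi_range_ms, "isi_range_ms")
  check_range(tap_delay_range_ms, "tap_delay_range_ms")
  if (is.null(params)) {
    params <- fusion_params(
      threshold = tap_amplitude / 8 + 6 * profile$accel_noise_sd,
      window_ms = touch_frame_ms(profile)
    )
  }
  stopifnot(inherits(params, "fusion_params"))

  dt <- accel_period_ms(profile)
  with_seed(seed, {
    delta1 <- stats::runif(n_trials, isi_range_ms[1L], isi_range_ms[2L])
    audio_lat <- pmax(0, stats::rnorm(n_trials, profile$audio_latency_ms[1L],
                                      profile$audio_latency_ms[2L]))
    vib_lat <- pmax(0, stats::rnorm(n_trials, profile$vib_latency_ms[1L],
                                    profile$vib_latency_ms[2L]))
    tap_delay <- stats::runif(n_trials, tap_delay_range_ms[1L],
                              tap_delay_range_ms[2L])
    trace_seeds <- sample.int(.Machine$integer.max, n_trials)
    touch_seeds <- sample.int(.Machine$integer.max, n_trials)

    t0 <- t1 <- t2 <- t0_ext <- t1_ext <- t2_ext <- numeric(n_trials)
    source <- character(n_trials)
    clock <- 0
    for (i in seq_len(n_trials)) {
      t0[i] <- clock
      t0_ext[i] <- t0[i] + audio_lat[i]
      t1[i] <- t0[i] + delta1[i]
      t1_ext[i] <- t1[i] + vib_lat[i]
      tap_true <- t1_ext[i] + tap_delay[i]

      # short trace around the tap, anchored on the free-running sample grid
      start <- floor((tap_true - 150) / dt) * dt
      trace <- simulate_accel_trace(tap_true, profile, duration_ms = 300,
                                    tap_amplitude = tap_amplitude,
                                    seed = trace_seeds[i], t0_ms = start)
      touch <- simulate_touch_events(tap_true, profile, seed = touch_seeds[i])
      peaks <- detect_taps(trace, params)
      fused <- fuse_rt(touch, peaks, stimulus_time = t1[i], params = params)
      t2[i] <- t1[i] + fused$rt_ms
      t2_ext[i] <- tap_true
      source[i] <- fused$source
      clock <- tap_true + 500
    }
    structure(
      data.frame(trial = seq_len(n_trials),
                 t0 = round_ms(t0), t1 = round_ms(t1), t2 = round_ms(t2),
                 t0_ext = round_ms(t0_ext), t1_ext = round_ms(t1_ext),
                 t2_ext = round_ms(t2_ext),
                 delta1_ms = round_ms(delta1),
                 source = source),
      class = c("bench_session", "data.frame")
    )
  })
}

#' Write / read a bench session CSV
#'
#' One header row; columns `trial, t0, t1, t2, t0_ext, t1_ext, t2_ext,
#' delta1_ms` (plus `source` when present); times in ms with "." decimal.
#'
#' @param records A `bench_session` data frame.
#' @param path File path.
#' @return `write_bench_csv` returns `path` invisibly; `read_bench_csv`
#'   returns a `bench_session` data frame.
#' @export
write_bench_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bench_csv
#' @export
read_bench_csv <- function(path) {
  if (!file.exists(path)) stop_input("bench CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t0", "t1", "t2", "t0_ext", "t1_ext", "t2_ext")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop_input("bench CSV missing column(s): %s", paste(missing, collapse = ", "))
  class(df) <- c("bench_session", "data.frame")
  df
}
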