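#' Onset detection and sensor-fusion parameters
#'
#' Parameters of the accelerometer onset detector and the touchscreen/
#' accelerometer fusion rule.
#'
#' @param alpha EWMA weight of past samples, in `[0, 1)`.  `alpha = 0`
#'   disables smoothing (the envelope is the raw absolute successive
#'   difference); values nearer 1 smooth more but blunt onsets.
#' @param threshold Envelope threshold, in acceleration units.  A tap is
#'   reported where the envelope first rises to or above this value.  See
#'   [calibrate_threshold()] for a data-driven choice.
#' @param refractory_ms Minimum separation between reported onsets, ms.
#'   Suppresses re-triggering on the tail of one physical tap; 50 ms is far
#'   below any plausible inter-response interval.
#' @param window_ms Fusion search-window length, ms.  Defaults to one
#'   120 Hz touchscreen frame (8.33 ms); set it to [touch_frame_ms()] of the
#'   device under test.
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(alpha = 0.5, threshold = 1, refractory_ms = 50,
                          window_ms = 1000 / 120) {
  assert_scalar_number(alpha, "alpha", lower = 0)
  if (alpha >= 1) stop_input("`alpha` must be < 1 (got %g)", alpha)
  assert_scalar_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  assert_scalar_number(refractory_ms, "refractory_ms", lower = 0)
  assert_scalar_number(window_ms, "window_ms", lower = 0, strict_lower = TRUE)
  structure(
    list(alpha = alpha, threshold = threshold,
         refractory_ms = refractory_ms, window_ms = window_ms),
    class = "fusion_params"
  )
}

#' @export
print.fusion_params <- function(x, ...) {
  cat(sprintf(
    "<fusion_params> alpha = %g, threshold = %g, refractory = %g ms, window = %.3g ms\n",
    x$alpha, x$threshold, x$refractory_ms, x$window_ms))
  invisible(x)
}

#' Acceleration vector magnitude
#'
#' Per-sample Euclidean norm of the 3-axis acceleration,
#' `sqrt(acc_x^2 + acc_y^2 + acc_z^2)`.  Working on the magnitude makes the
#' detector insensitive to how the device is held: a tap perturbs the norm
#' whatever the orientation.
#'
#' @param trace An [accel_trace][simulate_accel_trace] object, or a list/data
#'   frame with numeric `acc_x`, `acc_y`, `acc_z` of equal length.
#' @return Numeric vector, one value per sample.
#' @export
magnitude <- function(trace) {
  ax <- trace$acc_x; ay <- trace$acc_y; az <- trace$acc_z
  if (is.null(ax) || is.null(ay) || is.null(az))
    stop_input("`trace` must have acc_x, acc_y and acc_z components")
  n <- length(ax)
  if (n == 0L) stop_input("`trace` is empty")
  if (length(ay) != n || length(az) != n)
    stop_input("acceleration axis series must have equal length")
  sqrt(ax^2 + ay^2 + az^2)
}

#' EWMA envelope of a scalar series
#'
#' Exponentially weighted moving average of the absolute successive
#' difference,
#' `y[n] = |x[n-1] - x[n]| * (1 - alpha) + alpha * y[n-1]`, with `y[1] = 0`
#' (the envelope of an unseen past difference is zero).  The result is a
#' smoothed change-detector signal: flat wherever the input is locally
#' constant, and sharply elevated at transient jumps such as a finger-tap
#' impulse.  Implemented with a recursive linear filter; a naive
#' sample-by-sample loop gives identical values and serves as the test
#' oracle.
#'
#' @param x Numeric input series of length >= 2 (typically the acceleration
#'   [magnitude()] series).
#' @param alpha EWMA weight of past samples, in `[0, 1)`.
#' @param t Optional timestamps, same length as `x`.
#' @return An object of class `ewma_envelope`: list with `t`, `x` and the
#'   non-negative smoothed series `y`, all the same length as `x`.
#' @examples
#' ewma_envelope(c(0, 1, 1, 3), alpha = 0.5)$y  # 0, 0.5, 0.25, 1.125
#' @export
ewma_envelope <- function(x, alpha = 0.5, t = NULL) {
  if (!is.numeric(x) || length(x) < 2L)
    stop_input("`x` must be a numeric series of length >= 2")
  assert_scalar_number(alpha, "alpha", lower = 0)
  if (alpha >= 1) stop_input("`alpha` must be < 1 (got %g)", alpha)
  if (!is.null(t) && length(t) != length(x))
    stop_input("`t` must have the same length as `x`")
  d <- abs(diff(x))
  y <- c(0, as.numeric(stats::filter((1 - alpha) * d, alpha,
                                     method = "recursive")))
  structure(
    list(t = t %||% (seq_along(x) - 1), x = x, y = y),
    class = "ewma_envelope"
  )
}

#' @export
print.ewma_envelope <- function(x, ...) {
  cat(sprintf("<ewma_envelope> %d samples, y in [%.4g, %.4g]\n",
              length(x$y), min(x$y), max(x$y)))
  invisible(x)
}

#' Calibrate the detector threshold from a tap-free baseline
#'
#' Estimates the envelope noise floor on a segment known to contain no taps
#' and returns `k` times its standard deviation.  This mirrors the usual
#' bench calibration step: record the idle device, set the threshold a safe
#' factor above micro-movement noise.
#'
#' @param env An [ewma_envelope()] whose first `baseline_ms` are tap-free.
#' @param baseline_ms Length of the baseline segment, ms (default 500).
#' @param k Multiplier on the baseline SD (default 8).
#' @return A threshold value suitable for [fusion_params()].
#' @export
calibrate_threshold <- function(env, baseline_ms = 500, k = 8) {
  stopifnot(inherits(env, "ewma_envelope"))
  assert_scalar_number(k, "k", lower = 0, strict_lower = TRUE)
  base <- env$y[env$t <= env$t[1L] + baseline_ms]
  s <- stats::sd(base)
  if (!is.finite(s) || s == 0)
    stop_input(paste0("baseline envelope has zero variance; ",
                      "supply an explicit threshold instead"))
  k * s
}

#' Detect tap onsets by envelope thresholding
#'
#' Reports an onset at every sample where the envelope crosses from below to
#' at-or-above the threshold, then suppresses further reports for
#' `refractory_ms`.  The reported timestamp is the first crossing sample --
#' the onset of the transient, which is the proxy for physical contact --
#' not the envelope apex.
#'
#' @param env An [ewma_envelope()] with timestamps in ms.
#' @param params A [fusion_params()].
#' @return Sorted numeric vector of onset times in ms (possibly empty);
#'   consecutive elements are separated by at least `refractory_ms`.
#' @export
detect_peaks <- function(env, params = fusion_params()) {
  stopifnot(inherits(env, "ewma_envelope"), inherits(params, "fusion_params"))
  y <- env$y
  above <- y >= params$threshold
  rising <- above & !c(FALSE, above[-length(above)])
  idx <- which(rising)
  if (length(idx) == 0L) return(numeric(0))
  times <- env$t[idx]
  kept <- times[1L]
  last <- times[1L]
  for (tm in times[-1L]) {
    if (tm - last >= params$refractory_ms) {
      kept <- c(kept, tm)
      last <- tm
    }
  }
  kept
}

#' Fuse a touchscreen event with accelerometer onsets
#'
#' The touchscreen supplies a reliable but coarse event timestamp (quantized
#' to the frame grid and delayed by the OS pipeline); the accelerometer
#' supplies fine-grained onset candidates.  Within a search window of one
#' frame period ending at the logged touch time, the most recent (latest)
#' accelerometer onset supersedes the touchscreen timestamp; with no onset in
#' the window the logged time is used unchanged.  The fused response time can
#' therefore never exceed the touchscreen-only response time.
#'
#' @param touch A one-row data frame with `logged_time_ms` (as produced by
#'   [simulate_touch_events()]) or a single numeric logged time in ms.
#' @param peaks Numeric vector of accelerometer onset times from
#'   [detect_peaks()].
#' @param stimulus_time Stimulus onset in ms; must precede the logged touch.
#' @param params A [fusion_params()]; `window_ms` is the search-window
#'   length.
#' @return List with `rt_ms` (fused RT = response time - stimulus time),
#'   `response_time_ms`, and `source` (`"accelerometer"` or
#'   `"touchscreen"`).
#' @export
fuse_rt <- function(touch, peaks, stimulus_time, params = fusion_params()) {
  stopifnot(inherits(params, "fusion_params"))
  logged <- if (is.data.frame(touch) || is.list(touch)) {
    touch$logged_time_ms[1L]
  } else {
    as.numeric(touch)[1L]
  }
  if (!is.numeric(logged) || !is.finite(logged))
    stop_input("`touch` must carry a finite logged_time_ms")
  assert_scalar_number(stimulus_time, "stimulus_time")
  if (stimulus_time >= logged)
    stop_input("stimulus_time (%g) must precede the logged touch (%g)",
               stimulus_time, logged)
  in_window <- peaks[peaks >= logged - params$window_ms & peaks <= logged]
  if (length(in_window) > 0L) {
    response <- max(in_window)
    source <- "accelerometer"
  } else {
    response <- logged
    source <- "touchscreen"
  }
  list(rt_ms = response - stimulus_time,
       response_time_ms = response,
       source = source)
}

#' Run the full onset detector on an accelerometer trace
#'
#' Convenience wrapper: magnitude, EWMA envelope, threshold peak detection.
#'
#' @param trace An [accel_trace][simulate_accel_trace].
#' @param params A [fusion_params()].
#' @return Sorted numeric vector of detected onset times in ms.
#' @export
detect_taps <- function(trace, params = fusion_params()) {
  env <- ewma_envelope(magnitude(trace), alpha = params$alpha, t = trace$t)
  detect_peaks(env, params)
}
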