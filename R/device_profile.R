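#' Device profile
#'
#' A declarative description of a smartphone's timing-relevant hardware:
#' sensor sampling rates, stimulus-delivery latencies and touchscreen
#' pipeline latency.  Profiles drive every simulator in the package; they are
#' static declarations (what a data sheet or a bench measurement says about
#' the device), never queried from hardware at run time.
#'
#' Latencies are given as `c(mean, sd)` pairs in milliseconds: the mean is the
#' systematic offset between a software command and the physical event, the sd
#' the trial-to-trial jitter around it.  `has_low_latency` and `has_pro`
#' mirror the Android audio feature flags that correlate with good timing
#' performance; they are carried as metadata only.
#'
#' @param name Device label.
#' @param accel_rate_hz Accelerometer sampling rate (samples/s).
#' @param touch_rate_hz Touchscreen scan rate (frames/s); taps are reported on
#'   this frame grid.
#' @param audio_latency_ms Length-2 numeric `c(mean, sd)`: delay from audio
#'   command to audible onset, ms.
#' @param vib_latency_ms Length-2 numeric `c(mean, sd)`: delay from vibration
#'   command to motor onset, ms.
#' @param touch_pipeline_latency_ms Length-2 numeric `c(mean, sd)`: delay from
#'   physical screen contact to the OS-visible touch event, before frame
#'   quantization, ms.
#' @param accel_noise_sd Standard deviation of per-axis accelerometer noise,
#'   in acceleration units (m/s^2).
#' @param has_low_latency,has_pro Declared audio feature flags.
#' @return An object of class `device_profile`.
#' @examples
#' p <- device_profile("bench", accel_rate_hz = 500, touch_rate_hz = 120)
#' p
#' @seealso [read_device_profiles()] for loading profiles from a YAML file,
#'   [bundled_device_profiles()] for the shipped example profiles.
#' @export
device_profile <- function(name = "device",
                           accel_rate_hz = 500,
                           touch_rate_hz = 120,
                           audio_latency_ms = c(0, 0),
                           vib_latency_ms = c(0, 0),
                           touch_pipeline_latency_ms = c(0, 0),
                           accel_noise_sd = 0,
                           has_low_latency = FALSE,
                           has_pro = FALSE) {
  assert_scalar_number(accel_rate_hz, "accel_rate_hz", lower = 0, strict_lower = TRUE)
  assert_scalar_number(touch_rate_hz, "touch_rate_hz", lower = 0, strict_lower = TRUE)
  for (nm in c("audio_latency_ms", "vib_latency_ms", "touch_pipeline_latency_ms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)))
      stop_input("`%s` must be a finite numeric c(mean, sd)", nm)
    if (v[1L] < 0) stop_input("`%s` mean must be >= 0", nm)
    if (v[2L] < 0) stop_input("`%s` sd must be >= 0", nm)
  }
  assert_scalar_number(accel_noise_sd, "accel_noise_sd", lower = 0)
  structure(
    list(
      name = as.character(name)[1L],
      accel_rate_hz = accel_rate_hz,
      touch_rate_hz = touch_rate_hz,
      audio_latency_ms = unname(audio_latency_ms),
      vib_latency_ms = unname(vib_latency_ms),
      touch_pipeline_latency_ms = unname(touch_pipeline_latency_ms),
      accel_noise_sd = accel_noise_sd,
      has_low_latency = isTRUE(has_low_latency),
      has_pro = isTRUE(has_pro)
    ),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile> %s\n", x$name))
  cat(sprintf("  accelerometer: %g Hz (%.3g ms resolution), noise sd %g\n",
              x$accel_rate_hz, 1000 / x$accel_rate_hz, x$accel_noise_sd))
  cat(sprintf("  touchscreen:   %g Hz (%.3g ms frame)\n",
              x$touch_rate_hz, 1000 / x$touch_rate_hz))
  cat(sprintf("  latency ms (mean/sd): audio %g/%g, vibration %g/%g, touch pipeline %g/%g\n",
              x$audio_latency_ms[1L], x$audio_latency_ms[2L],
              x$vib_latency_ms[1L], x$vib_latency_ms[2L],
              x$touch_pipeline_latency_ms[1L], x$touch_pipeline_latency_ms[2L]))
  cat(sprintf("  flags: low-latency audio = %s, pro audio = %s\n",
              x$has_low_latency, x$has_pro))
  invisible(x)
}

#' Touchscreen frame period of a device profile
#'
#' One touchscreen scan period, `1000 / touch_rate_hz` ms.  This is both the
#' quantization step of touchscreen-only RT logging and the default fusion
#' search-window length.
#'
#' @param profile A [device_profile()].
#' @return Frame period in ms.
#' @export
touch_frame_ms <- function(profile) {
  stopifnot(inherits(profile, "device_profile"))
  1000 / profile$touch_rate_hz
}

#' Accelerometer sample period of a device profile
#'
#' @param profile A [device_profile()].
#' @return Sample period in ms (`1000 / accel_rate_hz`), the temporal
#'   resolution of accelerometer-based onset timestamps.
#' @export
accel_period_ms <- function(profile) {
  stopifnot(inherits(profile, "device_profile"))
  1000 / profile$accel_rate_hz
}

#' Read device profiles from a YAML config file
#'
#' The file maps profile names to fields of [device_profile()]; latency
#' entries may be written either as `[mean, sd]` pairs or as
#' `{mean: ..., sd: ...}` maps.
#'
#' @param path Path to a YAML file.
#' @return Named list of `device_profile` objects.
#' @export
read_device_profiles <- function(path) {
  if (!file.exists(path)) stop_input("profile file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)))
    stop_input("profile file must map profile names to field lists: %s", path)
  as_pair <- function(v) {
    if (is.null(v)) return(c(0, 0))
    if (is.list(v)) return(c(v$mean %||% 0, v$sd %||% 0))
    if (length(v) == 1L) return(c(v, 0))
    c(v[1L], v[2L])
  }
  out <- lapply(names(raw), function(nm) {
    f <- raw[[nm]]
    device_profile(
      name = f$name %||% nm,
      accel_rate_hz = f$accel_rate_hz %||% 500,
      touch_rate_hz = f$touch_rate_hz %||% 120,
      audio_latency_ms = as_pair(f$audio_latency_ms),
      vib_latency_ms = as_pair(f$vib_latency_ms),
      touch_pipeline_latency_ms = as_pair(f$touch_pipeline_latency_ms),
      accel_noise_sd = f$accel_noise_sd %||% 0,
      has_low_latency = isTRUE(f$has_low_latency),
      has_pro = isTRUE(f$has_pro)
    )
  })
  names(out) <- names(raw)
  out
}

#' Bundled example device profiles
#'
#' Loads the profiles shipped with the package: five consumer Android models
#' with their declared sensor rates and audio feature flags, plus an
#' idealized zero-latency `perfect` device useful as a simulation control.
#' The latency means/SDs attached to the five real models are synthetic
#' stand-ins consistent with their declared audio round-trip latencies, not
#' bench measurements; they exist so the simulators have plausible inputs.
#'
#' @return Named list of `device_profile` objects.
#' @export
bundled_device_profiles <- function() {
  read_device_profiles(
    system.file("extdata", "device_profiles.yaml", package = "rtfusion",
                mustWork = TRUE)
  )
}
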