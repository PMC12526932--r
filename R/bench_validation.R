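# Timing accuracy/precision statistics and device suitability.

#' Noise floor of an external measurement chain
#'
#' An external validation chain (audio interface + detection software) has
#' its own round-trip timing variability; the one-way noise floor is half
#' the round trip.  With the typical 3 ms round-trip variability of an
#' audio-interface chain the floor is 1.5 ms: delay variations smaller than
#' this cannot be attributed to the device under test.
#'
#' @param round_trip_ms Round-trip timing variability of the chain, ms
#'   (default `measurement_chain_round_trip_ms`).
#' @return One-way noise floor in ms.
#' @examples
#' chain_noise_floor_ms()  # 1.5
#' @export
chain_noise_floor_ms <- function(round_trip_ms = measurement_chain_round_trip_ms) {
  assert_scalar_number(round_trip_ms, "round_trip_ms", lower = 0)
  round_trip_ms / 2
}

#' @rdname chain_noise_floor_ms
#' @export
measurement_chain_round_trip_ms <- 3

#' Timing summary (accuracy and precision of timing deltas)
#'
#' Container for the standard reporting shape of stimulus-timing validation:
#' Mean delta (accuracy -- a stable offset, correctable in software), Min and
#' Max delta, and SD delta (precision -- the trial-to-trial jitter that
#' software cannot correct and that limits experimental usability).
#'
#' @param deltas Numeric vector of timing differences, ms.
#' @param label Optional metric label.
#' @return Object of class `timing_summary`: list with `label`,
#'   `mean_delta_ms`, `min_delta_ms`, `max_delta_ms`, `sd_delta_ms`
#'   (sample, n-1 denominator; `NA` when n < 2) and `n`.
#' @export
timing_summary <- function(deltas, label = "delta") {
  deltas <- as.numeric(deltas)
  if (length(deltas) < 1L || any(!is.finite(deltas)))
    stop_input("`deltas` must be a non-empty finite numeric vector")
  structure(
    list(label = label,
         mean_delta_ms = mean(deltas),
         min_delta_ms = min(deltas),
         max_delta_ms = max(deltas),
         sd_delta_ms = sample_sd(deltas),
         n = length(deltas)),
    class = "timing_summary"
  )
}

#' @export
print.timing_summary <- function(x, ...) {
  cat(sprintf(
    "<timing_summary> %s (n = %d)\n  Mean D = %+.3f ms  Min D = %+.3f ms  Max D = %+.3f ms  SD D = %.3f ms\n",
    x$label, x$n, x$mean_delta_ms, x$min_delta_ms, x$max_delta_ms,
    x$sd_delta_ms))
  invisible(x)
}

#' @export
as.data.frame.timing_summary <- function(x, ...) {
  data.frame(label = x$label, mean_delta_ms = x$mean_delta_ms,
             min_delta_ms = x$min_delta_ms, max_delta_ms = x$max_delta_ms,
             sd_delta_ms = x$sd_delta_ms, n = x$n)
}

#' Accuracy/precision of unisensory serial stimulus delivery
#'
#' For a train of stimulus onsets delivered at a nominal inter-stimulus
#' interval, measures each successive interval and summarizes the deviations
#' `interval - intended_isi`.  This is the serial-delivery validation
#' protocol: stimuli every `intended_isi` ms for several minutes, intervals
#' measured externally.
#'
#' @param onset_times_ms Sorted numeric vector of at least 3 measured onset
#'   times, ms.
#' @param intended_isi_ms The scheduled inter-stimulus interval, ms.
#' @return A [timing_summary()] over the `length(onset_times_ms) - 1`
#'   interval deviations.
#' @examples
#' unisensory_interval_stats(c(0, 510, 1020), 500)  # Mean D = +10, SD D = 0
#' @export
unisensory_interval_stats <- function(onset_times_ms, intended_isi_ms) {
  onset_times_ms <- as.numeric(onset_times_ms)
  if (length(onset_times_ms) < 3L)
    stop_input("need at least 3 onsets")
  if (is.unsorted(onset_times_ms))
    stop_input("onset times must be sorted ascending")
  assert_scalar_number(intended_isi_ms, "intended_isi_ms", lower = 0,
                       strict_lower = TRUE)
  deltas <- diff(onset_times_ms) - intended_isi_ms
  timing_summary(deltas, label = sprintf("ISI - %g ms", intended_isi_ms))
}

#' Internal-vs-external paired interval deltas of a bench session
#'
#' Per trial, compares the intervals the device *believes* it produced with
#' the intervals that *physically* occurred:
#' * sync delta (AA'): `(t1 - t0) - (t1' - t0')` -- error in the scheduled
#'   audio-to-vibration delay;
#' * rt delta (BB'): `(t2 - t1) - (t2' - t1')` -- error in the logged
#'   reaction time.
#'
#' The mean of each list is the device's accuracy on that interval, the SD
#' its precision.
#'
#' @param records A `bench_session` data frame (see
#'   [simulate_bench_session()] / [read_bench_csv()]) with at least 2 rows.
#' @return List with numeric vectors `sync` and `rt`, one value per trial.
#' @export
bench_deltas <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) stop_input("need at least 2 bench records")
  need <- c("t0", "t1", "t2", "t0_ext", "t1_ext", "t2_ext")
  for (nm in need) {
    if (is.null(records[[nm]]))
      stop_input("bench records missing column `%s`", nm)
    bad <- which(!is.finite(records[[nm]]))
    if (length(bad) > 0L)
      stop_input("missing/invalid `%s` in trial %d", nm, bad[1L])
  }
  list(
    sync = (records$t1 - records$t0) - (records$t1_ext - records$t0_ext),
    rt = (records$t2 - records$t1) - (records$t2_ext - records$t1_ext)
  )
}

#' Classify a device's suitability for audio-tactile RT paradigms
#'
#' A device is suitable when the trial-to-trial jitter of both its
#' audio-tactile synchronization and its RT logging stays at or below a
#' precision threshold.  The 10 ms default is an order of magnitude below the
#' typical human threshold for detecting multisensory asynchrony
#' (~50-100 ms); the boundary is inclusive.
#'
#' @param sync_sd_ms SD of the sync (AA') deltas, ms.
#' @param rt_sd_ms SD of the rt (BB') deltas, ms.
#' @param threshold_ms Precision cutoff, ms (default 10).
#' @return Object of class `device_verdict`: list with `sync_precision_ms`,
#'   `rt_precision_ms`, `threshold_ms`, `suitable`.
#' @examples
#' classify_device(5, 7)$suitable    # TRUE
#' classify_device(12, 3)$suitable   # FALSE
#' classify_device(10, 10)$suitable  # TRUE (boundary inclusive)
#' @export
classify_device <- function(sync_sd_ms, rt_sd_ms, threshold_ms = 10) {
  assert_scalar_number(sync_sd_ms, "sync_sd_ms", lower = 0)
  assert_scalar_number(rt_sd_ms, "rt_sd_ms", lower = 0)
  assert_scalar_number(threshold_ms, "threshold_ms", lower = 0,
                       strict_lower = TRUE)
  structure(
    list(sync_precision_ms = sync_sd_ms,
         rt_precision_ms = rt_sd_ms,
         threshold_ms = threshold_ms,
         suitable = sync_sd_ms <= threshold_ms && rt_sd_ms <= threshold_ms),
    class = "device_verdict"
  )
}

#' @export
print.device_verdict <- function(x, ...) {
  cat(sprintf(
    "<device_verdict> sync precision = %.3f ms, rt precision = %.3f ms (threshold %g ms)\n  %s\n",
    x$sync_precision_ms, x$rt_precision_ms, x$threshold_ms,
    if (x$suitable) "SUITABLE for audio-tactile RT paradigms"
    else "NOT suitable for audio-tactile RT paradigms"))
  invisible(x)
}

#' Validate a device profile on a simulated bench
#'
#' Runs [simulate_bench_session()], computes [bench_deltas()] and summarizes
#' them, then applies [classify_device()] to the two precisions.
#'
#' @param profile A [device_profile()].
#' @param n_trials Number of bench trials.
#' @param seed Integer seed.
#' @param threshold_ms Precision cutoff for the verdict.
#' @param ... Passed on to [simulate_bench_session()].
#' @return List with `records`, `sync_summary`, `rt_summary` (both
#'   [timing_summary()]) and `verdict` ([classify_device()]).
#' @export
validate_device <- function(profile, n_trials = 1000, seed = 1,
                            threshold_ms = 10, ...) {
  records <- simulate_bench_session(profile, n_trials = n_trials,
                                    seed = seed, ...)
  d <- bench_deltas(records)
  sync_summary <- timing_summary(d$sync, label = "sync AA'")
  rt_summary <- timing_summary(d$rt, label = "rt BB'")
  verdict <- classify_device(sync_summary$sd_delta_ms,
                             rt_summary$sd_delta_ms,
                             threshold_ms = threshold_ms)
  list(records = records, sync_summary = sync_summary,
       rt_summary = rt_summary, verdict = verdict)
}

#' Write a timing-summary CSV
#'
#' One row per metric, columns in the conventional order
#' `metric, mean_delta_ms, min_delta_ms, max_delta_ms, sd_delta_ms, n`.
#'
#' @param summaries A list of [timing_summary()] objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_timing_summary_csv <- function(summaries, path) {
  if (inherits(summaries, "timing_summary")) summaries <- list(summaries)
  rows <- do.call(rbind, lapply(summaries, as.data.frame))
  names(rows)[1L] <- "metric"
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
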