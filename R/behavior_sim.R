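# Synthetic participant cohorts with the statistical structure the RT
# analysis assumes: lognormal within-cell RTs, tactile expectancy (RTs
# decline with tactile delay), and a looming facilitation at the longest
# delays.

#' Cohort simulation parameters
#'
#' Describes a synthetic participant sample.  Within a cell, RTs are
#' lognormal with median `base_median_rt_ms[delay] + participant offset -
#' looming_effect_ms[delay]` (the effect subtracted only in the looming
#' condition) and log-scale shape `sigma_log`.  The facilitation is applied
#' on the millisecond scale -- it shifts the lognormal's median -- so the
#' injected effect equals the headline ms quantity the analysis should
#' recover.
#'
#' Defaults: medians fall from 420 ms (T1) to 330 ms (T6), emulating the
#' expectancy-driven decline of RT along the trial; facilitation is 0 at
#' T1-T2 and 22.5 ms at T3-T6 (the center of the 20-25 ms band typical of
#' looming sounds entering peripersonal space); `sigma_log = 0.15` gives the
#' right-skewed within-cell distributions characteristic of RT data;
#' participants differ by a Gaussian offset with SD 30 ms; 1.4% of
#' experimental trials are misses.
#'
#' @param n_participants Number of participants (default 18).
#' @param base_median_rt_ms Named per-delay vector (T1..T6) of fixed-condition
#'   median RTs, ms; must be strictly decreasing.
#' @param looming_effect_ms Named per-delay facilitation vector, ms; each
#'   entry must be nonnegative and smaller than its median.
#' @param sigma_log Lognormal shape (SD of ln RT) within a cell; >= 0.
#' @param participant_sd_ms Between-participant SD of the median offset, ms.
#' @param miss_prob Per-trial miss probability in `[0, 1)`.
#' @param false_alarm_prob Per-catch-trial false-alarm probability in
#'   `[0, 1)`; default 0 (off).
#' @param seed Integer seed.
#' @return Object of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 18,
                          base_median_rt_ms = c(T1 = 420, T2 = 400, T3 = 375,
                                                T4 = 355, T5 = 340, T6 = 330),
                          looming_effect_ms = c(T1 = 0, T2 = 0, T3 = 22.5,
                                                T4 = 22.5, T5 = 22.5, T6 = 22.5),
                          sigma_log = 0.15,
                          participant_sd_ms = 30,
                          miss_prob = 0.014,
                          false_alarm_prob = 0,
                          seed = 1) {
  if (!is.numeric(n_participants) || n_participants < 1)
    stop_input("`n_participants` must be >= 1")
  labels <- names(tactile_delays_ms)
  for (nm in c("base_median_rt_ms", "looming_effect_ms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != length(labels))
      stop_input("`%s` must be a numeric vector over %s", nm,
                 paste(labels, collapse = ", "))
  }
  if (is.null(names(base_median_rt_ms))) names(base_median_rt_ms) <- labels
  if (is.null(names(looming_effect_ms))) names(looming_effect_ms) <- labels
  if (any(base_median_rt_ms <= 0))
    stop_input("all `base_median_rt_ms` must be > 0")
  if (any(diff(base_median_rt_ms[labels]) >= 0))
    stop_input("`base_median_rt_ms` must be strictly decreasing across T1..T6")
  if (any(looming_effect_ms < 0) ||
      any(looming_effect_ms >= base_median_rt_ms))
    stop_input("`looming_effect_ms` must be >= 0 and < the matching median")
  assert_scalar_number(sigma_log, "sigma_log", lower = 0)
  assert_scalar_number(participant_sd_ms, "participant_sd_ms", lower = 0)
  assert_scalar_number(miss_prob, "miss_prob", lower = 0)
  if (miss_prob >= 1) stop_input("`miss_prob` must be < 1")
  assert_scalar_number(false_alarm_prob, "false_alarm_prob", lower = 0)
  if (false_alarm_prob >= 1) stop_input("`false_alarm_prob` must be < 1")
  structure(
    list(n_participants = as.integer(n_participants),
         base_median_rt_ms = base_median_rt_ms[labels],
         looming_effect_ms = looming_effect_ms[labels],
         sigma_log = sigma_log,
         participant_sd_ms = participant_sd_ms,
         miss_prob = miss_prob,
         false_alarm_prob = false_alarm_prob,
         seed = as.integer(seed)),
    class = "cohort_params"
  )
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf("<cohort_params> %d participants, sigma_log = %g, participant sd = %g ms, miss prob = %g\n",
              x$n_participants, x$sigma_log, x$participant_sd_ms, x$miss_prob))
  cat("  base medians (ms):", paste(sprintf("%s=%g", names(x$base_median_rt_ms),
                                            x$base_median_rt_ms), collapse = " "), "\n")
  cat("  looming effect (ms):", paste(sprintf("%s=%g", names(x$looming_effect_ms),
                                              x$looming_effect_ms), collapse = " "), "\n")
  invisible(x)
}

#' Simulate a participant cohort over a session schedule
#'
#' Runs every participant through the same schedule.  Experimental trials
#' yield a lognormal RT (see [cohort_params()]) or, with probability
#' `miss_prob`, a miss; catch trials yield no RT (a correct rejection, or a
#' false alarm at rate `false_alarm_prob` if enabled).  RTs are rounded to
#' 0.001 ms so session CSVs round-trip exactly.  The output is seed-
#' deterministic.
#'
#' @param schedule A [generate_schedule()] result.
#' @param params A [cohort_params()].
#' @return Object of class `cohort_sessions`: long data frame with a
#'   `participant` column (`"P01"`, ...) followed by the session CSV
#'   columns.  The injected ground truth is attached as attribute
#'   `ground_truth`.
#' @export
simulate_cohort <- function(schedule, params = cohort_params()) {
  stopifnot(is.data.frame(schedule), inherits(params, "cohort_params"))
  n_trials <- nrow(schedule)
  exp_idx <- !schedule$is_catch
  labels <- schedule$delay_label

  with_seed(params$seed, {
    offsets <- stats::rnorm(params$n_participants, 0, params$participant_sd_ms)
    out <- vector("list", params$n_participants)
    for (p in seq_len(params$n_participants)) {
      rt <- rep(NA_real_, n_trials)
      response <- rep("correct_rejection", n_trials)
      med <- params$base_median_rt_ms[labels] + offsets[p]
      med <- med - ifelse(schedule$movement == "looming",
                          params$looming_effect_ms[labels], 0)
      med <- pmax(med, 50)  # keep medians physiological even at extreme offsets
      z <- stats::rnorm(n_trials)
      draw <- med * exp(params$sigma_log * z)
      miss <- stats::runif(n_trials) < params$miss_prob
      hit <- exp_idx & !miss
      rt[hit] <- round_ms(draw[hit])
      response[hit] <- "hit"
      response[exp_idx & miss] <- "miss"
      if (params$false_alarm_prob > 0) {
        fa <- !exp_idx & stats::runif(n_trials) < params$false_alarm_prob
        response[fa] <- "false_alarm"
      }
      out[[p]] <- data.frame(
        participant = sprintf("P%02d", p),
        block = schedule$block, trial = schedule$trial,
        movement = schedule$movement, delay_label = schedule$delay_label,
        delay_ms = schedule$delay_ms, distance_cm = schedule$distance_cm,
        is_catch = schedule$is_catch,
        rt_ms = rt, response = response,
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    structure(res, class = c("cohort_sessions", "data.frame"),
              ground_truth = params)
  })
}

#' @export
print.cohort_sessions <- function(x, ...) {
  np <- length(unique(x$participant))
  cat(sprintf("<cohort_sessions> %d participants x %d trials (%d rows)\n",
              np, nrow(x) / np, nrow(x)))
  invisible(x)
}

#' Write a simulated cohort to one session CSV per participant
#'
#' Also writes `ground_truth.json` with the injected simulation parameters,
#' so recovery analyses can compare estimates against truth.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the session CSV paths, invisibly.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_sessions"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- unique(cohort$participant)
  paths <- vapply(ids, function(id) {
    path <- file.path(dir, paste0("session_", id, ".csv"))
    write_session_csv(cohort[cohort$participant == id, , drop = FALSE], path)
    path
  }, character(1L))
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(unclass(gt), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(unname(paths))
}

#' Read a directory of session CSVs into a cohort
#'
#' Participant ids are taken from the file names (`session_<id>.csv`).
#'
#' @param dir Directory containing `session_*.csv` files.
#' @return A `cohort_sessions` data frame.
#' @export
read_cohort_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^session_.*\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop_input("no session_*.csv files found in %s", dir)
  out <- lapply(files, function(f) {
    df <- read_session_csv(f)
    id <- sub("^session_(.*)\\.csv$", "\\1", basename(f))
    cbind(participant = id, df, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("cohort_sessions", "data.frame"))
}
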