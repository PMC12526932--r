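# Audio-tactile peripersonal-space paradigm: tactile delays, delay-to-distance
# mapping, session schedule generation, and session CSV I/O.

#' Tactile delays and looming-source distances of the paradigm
#'
#' The six tactile onset asynchronies (ms from sound onset) and, for the
#' looming sound, the simulated source distance at tactile onset.  The
#' distances follow a logarithmic scale from 640 cm down to 20 cm; in the
#' fixed condition the source stays at 640 cm throughout.  The sound lasts
#' 3250 ms, so every delay falls within the sound.
#'
#' @format `tactile_delays_ms` is a named numeric vector (T1..T6);
#'   `looming_distances_cm` likewise.
#' @export
tactile_delays_ms <- c(T1 = 105, T2 = 1625, T3 = 2385,
                       T4 = 2765, T5 = 2955, T6 = 3050)

#' @rdname tactile_delays_ms
#' @export
looming_distances_cm <- c(T1 = 640, T2 = 320, T3 = 160,
                          T4 = 80, T5 = 40, T6 = 20)

#' @rdname tactile_delays_ms
#' @export
sound_duration_ms <- 3250

#' @rdname tactile_delays_ms
#' @export
fixed_distance_cm <- 640

#' Map a tactile delay to the sound-source distance at tactile onset
#'
#' In the looming condition the source approaches from 640 cm to 20 cm over
#' the sound's duration, so longer tactile delays correspond to nearer
#' source positions (T1 -> 640 cm ... T6 -> 20 cm).  In the fixed condition
#' the source remains static at 640 cm whatever the delay.
#'
#' @param delay_label Character vector of labels in `"T1".."T6"`.
#' @param movement `"fixed"` or `"looming"` (recycled).
#' @return Numeric vector of distances in cm.
#' @examples
#' delay_to_distance("T6", "looming")  # 20
#' delay_to_distance("T4", "fixed")    # 640
#' @export
delay_to_distance <- function(delay_label, movement) {
  delay_label <- as.character(delay_label)
  movement <- match_movement(movement)
  bad <- setdiff(delay_label, names(looming_distances_cm))
  if (length(bad) > 0L)
    stop_input("unknown delay label(s): %s", paste(bad, collapse = ", "))
  out <- unname(looming_distances_cm[delay_label])
  n <- max(length(delay_label), length(movement))
  out <- rep_len(out, n)
  movement <- rep_len(movement, n)
  out[movement == "fixed"] <- fixed_distance_cm
  out
}

match_movement <- function(movement) {
  movement <- as.character(movement)
  if (!all(movement %in% c("fixed", "looming")))
    stop_input("`movement` must be \"fixed\" or \"looming\"")
  movement
}

#' Generate a peripersonal-space session schedule
#'
#' Builds the block structure of the audio-tactile detection task.  Each
#' block holds 4 repetitions of each of the 12 experimental cells
#' (2 sound-movement conditions x 6 tactile delays = 48 experimental trials)
#' plus 24 catch trials (sound but no tactile stimulus; 12 per movement
#' condition), uniformly shuffled within the block under the seed.  The
#' default 6 blocks give 432 trials: 288 experimental (24 repetitions per
#' cell) and 144 catch (33.3%).
#'
#' Every trial carries a 300 ms pre-sound silence and a post-sound silence
#' drawn uniformly (integer ms) from 1000-1400 ms.
#'
#' @param n_blocks Number of blocks (default 6).
#' @param seed Integer seed governing trial order and silence draws.
#' @param reps_per_cell Experimental repetitions of each (movement x delay)
#'   cell per block (default 4).
#' @param catch_per_block Catch trials per block (default 24, split evenly
#'   between the two movement conditions).
#' @return Object of class `session_schedule`: data frame with one row per
#'   trial and columns `block`, `trial` (global index), `index_in_block`,
#'   `movement`, `delay_label`, `delay_ms`, `distance_cm`, `is_catch`,
#'   `pre_silence_ms`, `post_silence_ms`.  Catch trials have `NA` delay and
#'   distance.  Attributes `n_blocks` and `seed` record the design.
#' @examples
#' sched <- generate_schedule(seed = 42)
#' nrow(sched)            # 432
#' sum(!sched$is_catch)   # 288
#' @export
generate_schedule <- function(n_blocks = 6, seed = 1, reps_per_cell = 4,
                              catch_per_block = 24) {
  if (!is.numeric(n_blocks) || n_blocks < 1)
    stop_input("`n_blocks` must be >= 1")
  n_blocks <- as.integer(n_blocks)
  reps_per_cell <- as.integer(reps_per_cell)
  catch_per_block <- as.integer(catch_per_block)
  if (catch_per_block %% 2L != 0L)
    stop_input("`catch_per_block` must be even (split across movement conditions)")

  cells <- expand.grid(movement = c("fixed", "looming"),
                       delay_label = names(tactile_delays_ms),
                       rep = seq_len(reps_per_cell),
                       stringsAsFactors = FALSE)
  block_template <- data.frame(
    movement = c(cells$movement,
                 rep(c("fixed", "looming"), each = catch_per_block / 2L)),
    delay_label = c(cells$delay_label,
                    rep(NA_character_, catch_per_block)),
    is_catch = c(rep(FALSE, nrow(cells)), rep(TRUE, catch_per_block)),
    stringsAsFactors = FALSE
  )

  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      blk <- block_template[sample.int(nrow(block_template)), , drop = FALSE]
      blk$block <- b
      blk$index_in_block <- seq_len(nrow(blk))
      blk
    })
    sched <- do.call(rbind, blocks)
    rownames(sched) <- NULL
    sched$trial <- seq_len(nrow(sched))
    sched$delay_ms <- unname(tactile_delays_ms[sched$delay_label])
    sched$distance_cm <- NA_real_
    exp_idx <- !sched$is_catch
    sched$distance_cm[exp_idx] <- delay_to_distance(
      sched$delay_label[exp_idx], sched$movement[exp_idx])
    sched$pre_silence_ms <- 300
    sched$post_silence_ms <- as.numeric(
      sample(1000:1400, nrow(sched), replace = TRUE))
    sched <- sched[, c("block", "trial", "index_in_block", "movement",
                       "delay_label", "delay_ms", "distance_cm", "is_catch",
                       "pre_silence_ms", "post_silence_ms")]
    structure(sched, class = c("session_schedule", "data.frame"),
              n_blocks = n_blocks, seed = as.integer(seed))
  })
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf(
    "<session_schedule> %d trials in %d block(s): %d experimental, %d catch (%.1f%%)\n",
    nrow(x), attr(x, "n_blocks") %||% length(unique(x$block)),
    sum(!x$is_catch), sum(x$is_catch), 100 * mean(x$is_catch)))
  invisible(x)
}

# Columns of the session CSV (one row per trial).
session_csv_columns <- c("block", "trial", "movement", "delay_label",
                         "delay_ms", "distance_cm", "is_catch", "rt_ms",
                         "response")

#' Write / read a session CSV
#'
#' One row per trial; comma-separated, header row, UTF-8, "." decimal.
#' Columns: `block, trial, movement, delay_label, delay_ms, distance_cm,
#' is_catch, rt_ms, response`.  Catch trials and misses leave `delay_*`,
#' `distance_cm` and/or `rt_ms` empty.  `response` is one of
#' `hit | miss | false_alarm | correct_rejection`.
#'
#' Times are stored to 0.001 ms and package generators emit values already
#' rounded to that precision, so `read_session_csv(write_session_csv(x))`
#' reproduces `x` exactly over these columns.
#'
#' @param session Data frame holding the columns above (a
#'   [generate_schedule()] result, optionally augmented with `rt_ms` and
#'   `response` by [simulate_cohort()]).  Missing `rt_ms`/`response` columns
#'   are written empty.
#' @param path File path.
#' @return `write_session_csv` returns `path` invisibly;
#'   `read_session_csv` returns a data frame with the columns above (plus
#'   nothing else), with a parse error naming the first offending line on
#'   malformed input.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(is.data.frame(session))
  out <- data.frame(
    block = as.integer(session$block),
    trial = as.integer(session$trial),
    movement = as.character(session$movement),
    delay_label = as.character(session$delay_label),
    delay_ms = round_ms(as.numeric(session$delay_ms)),
    distance_cm = as.numeric(session$distance_cm),
    is_catch = as.logical(session$is_catch),
    rt_ms = round_ms(as.numeric(session$rt_ms %||% rep(NA_real_, nrow(session)))),
    response = as.character(session$response %||% rep(NA_character_, nrow(session))),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) stop_input("session CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"),
                        colClasses = c(
                          block = "integer", trial = "integer",
                          movement = "character", delay_label = "character",
                          delay_ms = "numeric", distance_cm = "numeric",
                          is_catch = "logical", rt_ms = "numeric",
                          response = "character"))
  missing <- setdiff(session_csv_columns, names(df))
  if (length(missing) > 0L)
    stop_input("session CSV %s missing column(s): %s", path,
               paste(missing, collapse = ", "))
  df <- df[, session_csv_columns]
  # line numbers are 1-based data lines + 1 header line
  check <- function(bad, what) {
    if (any(bad))
      stop_input("session CSV %s: %s at line %d", path, what,
                 which(bad)[1L] + 1L)
  }
  check(!(df$movement %in% c("fixed", "looming")), "invalid movement flag")
  check(!df$is_catch & !(df$delay_label %in% names(tactile_delays_ms)),
        "experimental trial without a valid delay label")
  check(df$is_catch & !is.na(df$delay_label),
        "catch trial with a delay label")
  known <- !df$is_catch
  mism <- known & abs(df$delay_ms - unname(tactile_delays_ms[df$delay_label])) > 1e-9
  check(ifelse(is.na(mism), TRUE, mism) & known,
        "delay_ms inconsistent with delay_label")
  check(!is.na(df$rt_ms) & df$rt_ms <= 0, "non-positive RT")
  df
}
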