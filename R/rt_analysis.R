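# RT analysis pipeline: participant exclusion, RT filtering, log-transformed
# condition means, per-delay contrasts, and the repeated-measures ANOVA.

#' Per-participant miss rates
#'
#' Fraction of experimental (non-catch) trials answered with a miss,
#' expressed as a percentage.
#'
#' @param cohort A `cohort_sessions` data frame ([simulate_cohort()] or
#'   [read_cohort_dir()]).
#' @return Named numeric vector of miss percentages.
#' @export
miss_rates <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  exp_rows <- cohort[!cohort$is_catch, , drop = FALSE]
  rates <- tapply(exp_rows$response == "miss", exp_rows$participant, mean)
  100 * unlist(rates)
}

#' Exclude participants with outlying miss rates
#'
#' The default rule removes every participant whose miss rate exceeds the
#' sample mean plus 3 sample SDs, both computed on the *full* sample, in a
#' single pass (no iterative re-screening).  On a sample with mean 1.4% and
#' SD 2.0% the cutoff is 7.4%, so a participant missing 9.0% of trials is
#' excluded.  The rule is pluggable: pass a function mapping the named rate
#' vector to a logical keep-vector.
#'
#' @param rates Named numeric vector of per-participant miss percentages
#'   (length >= 2), e.g. from [miss_rates()].
#' @param rule `"mean_3sd"` (default) or a function `rates -> logical`.
#' @return List with `kept` (ids), `excluded` (ids), `cutoff` (NA for a
#'   custom rule), `mean`, `sd`.
#' @export
exclude_participants <- function(rates, rule = "mean_3sd") {
  if (length(rates) < 2L) stop_input("need at least 2 participants")
  if (is.null(names(rates))) names(rates) <- seq_along(rates)
  if (is.function(rule)) {
    keep <- rule(rates)
    cutoff <- NA_real_
  } else if (identical(rule, "mean_3sd")) {
    cutoff <- mean(rates) + 3 * stats::sd(rates)
    keep <- rates <= cutoff
  } else {
    stop_input("unknown exclusion rule: %s", as.character(rule)[1L])
  }
  list(kept = names(rates)[keep], excluded = names(rates)[!keep],
       cutoff = cutoff, mean = mean(rates), sd = stats::sd(rates))
}

#' Filter reaction times to a plausible window
#'
#' Keeps RT-bearing trials with `low <= rt <= high` (boundary inclusive);
#' RTs outside the window are too short (anticipations) or too long (lapses)
#' to reflect speeded tactile detection.  Trials without an RT (misses,
#' catch trials) pass through untouched and do not count toward the removed
#' fraction.
#'
#' @param records Data frame with an `rt_ms` column.
#' @param low,high Window bounds in ms, `0 < low < high` (defaults 100 and
#'   1000).
#' @return List with `records` (kept rows) and `removed_pct` (percentage of
#'   RT-bearing trials removed; 0 with a warning when there are none).
#' @export
filter_rts <- function(records, low = 100, high = 1000) {
  stopifnot(is.data.frame(records))
  assert_scalar_number(low, "low", lower = 0, strict_lower = TRUE)
  if (high <= low) stop_input("`high` must exceed `low`")
  has_rt <- !is.na(records$rt_ms)
  if (!any(has_rt)) {
    warning("no RT-bearing trials; nothing to filter")
    return(list(records = records, removed_pct = 0))
  }
  bad <- has_rt & (records$rt_ms < low | records$rt_ms > high)
  list(records = records[!bad, , drop = FALSE],
       removed_pct = 100 * sum(bad) / sum(has_rt))
}

#' Log-transformed condition means and looming facilitation
#'
#' RT distributions are right-skewed, so each RT is ln-transformed, averaged
#' per participant within each (movement x delay) cell, and the mean
#' back-transformed by exponentiation -- the cell geometric mean.  Group
#' cell means are arithmetic means of the participant values, with SEM
#' across participants.  Facilitation at each delay is the fixed-condition
#' group mean minus the looming-condition group mean: positive when the
#' looming sound speeds detection.
#'
#' @param records Data frame with `participant`, `movement`, `delay_label`
#'   and `rt_ms`; rows without an RT are ignored.  Every participant must
#'   contribute at least one RT to every cell.
#' @return Object of class `condition_summary`: list with
#'   * `cell_means`: participant x cell back-transformed means (long data
#'     frame `participant, movement, delay_label, mean_rt_ms`);
#'   * `group`: per-cell `movement, delay_label, mean_rt_ms, sem_ms, n`;
#'   * `facilitation`: per-delay `delay_label, facilitation_ms`.
#' @examples
#' df <- data.frame(participant = "P1", movement = "fixed",
#'                  delay_label = "T1", rt_ms = c(100, 400))
#' # geometric mean sqrt(100 * 400) = 200
#' @export
condition_means <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("participant", "movement", "delay_label", "rt_ms")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0L)
    stop_input("records missing column(s): %s", paste(missing, collapse = ", "))
  rts <- records[!is.na(records$rt_ms), need]
  if (any(rts$rt_ms <= 0)) stop_input("all RTs must be > 0")

  participants <- sort(unique(rts$participant))
  delays <- names(tactile_delays_ms)
  delays <- delays[delays %in% unique(rts$delay_label)]
  movements <- c("fixed", "looming")

  agg <- stats::aggregate(rt_ms ~ participant + movement + delay_label,
                          data = rts, FUN = function(v) exp(mean(log(v))))
  names(agg)[names(agg) == "rt_ms"] <- "mean_rt_ms"

  full <- expand.grid(participant = participants, movement = movements,
                      delay_label = delays, stringsAsFactors = FALSE)
  merged <- merge(full, agg, all.x = TRUE, sort = FALSE)
  empty <- which(is.na(merged$mean_rt_ms))
  if (length(empty) > 0L)
    stop_input("participant %s has no RTs in cell (%s, %s)",
               merged$participant[empty[1L]], merged$movement[empty[1L]],
               merged$delay_label[empty[1L]])
  merged <- merged[order(merged$participant,
                         match(merged$delay_label, delays),
                         merged$movement), ]
  rownames(merged) <- NULL

  sem <- function(v) stats::sd(v) / sqrt(length(v))
  grp <- do.call(rbind, lapply(delays, function(d) {
    do.call(rbind, lapply(movements, function(m) {
      v <- merged$mean_rt_ms[merged$movement == m & merged$delay_label == d]
      data.frame(movement = m, delay_label = d, mean_rt_ms = mean(v),
                 sem_ms = sem(v), n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(grp) <- NULL
  fac <- data.frame(
    delay_label = delays,
    facilitation_ms = vapply(delays, function(d) {
      grp$mean_rt_ms[grp$movement == "fixed" & grp$delay_label == d] -
        grp$mean_rt_ms[grp$movement == "looming" & grp$delay_label == d]
    }, numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(fac) <- NULL
  structure(list(cell_means = merged, group = grp, facilitation = fac),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %d participants, %d cells\n",
              length(unique(x$cell_means$participant)), nrow(x$group)))
  cat("facilitation (fixed - looming, ms):\n")
  print(x$facilitation, row.names = FALSE)
  invisible(x)
}

#' Two-way within-subject ANOVA on cell means
#'
#' Classical repeated-measures decomposition for the 2 (sound movement) x
#' k (delay) within-subject design: each effect is tested against its own
#' effect-by-subject interaction.  With n participants and 6 delays the
#' degrees of freedom are (1, n-1) for movement and (5, 5(n-1)) for delay
#' and the interaction.  Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.  Uncorrected df are reported by
#' default; `gg = TRUE` adds Greenhouse-Geisser epsilon-corrected p-values
#' for effects with more than 1 numerator df.
#'
#' @param cell_means Long data frame `participant, movement, delay_label,
#'   mean_rt_ms` (the `cell_means` element of [condition_means()]), one row
#'   per participant x cell -- a complete balanced design.
#' @param gg Add Greenhouse-Geisser correction columns (`epsilon`, `p_gg`)?
#' @return Data frame with one row per effect (`movement`, `delay`,
#'   `movement:delay`): `effect, df1, df2, ss_effect, ss_error, F, p,
#'   eta_p2` (plus `epsilon`, `p_gg` when `gg = TRUE`).
#' @export
rm_anova <- function(cell_means, gg = FALSE) {
  stopifnot(is.data.frame(cell_means))
  need <- c("participant", "movement", "delay_label", "mean_rt_ms")
  missing <- setdiff(need, names(cell_means))
  if (length(missing) > 0L)
    stop_input("cell_means missing column(s): %s",
               paste(missing, collapse = ", "))
  d <- cell_means
  d$participant <- factor(d$participant)
  d$movement <- factor(d$movement)
  d$delay <- factor(d$delay_label,
                    levels = intersect(names(tactile_delays_ms),
                                       unique(d$delay_label)))
  if (any(is.na(d$delay))) d$delay <- factor(d$delay_label)
  counts <- table(d$participant, d$movement, d$delay)
  if (any(counts != 1L))
    stop_input("design must be complete and balanced: one value per participant x movement x delay cell")

  fit <- stats::aov(mean_rt_ms ~ movement * delay +
                      Error(participant / (movement * delay)), data = d)
  s <- summary(fit)
  pull <- function(stratum, effect) {
    tab <- s[[stratum]][[1L]]
    rn <- trimws(rownames(tab))
    i <- match(effect, rn)
    j <- match("Residuals", rn)
    data.frame(effect = effect,
               df1 = tab$Df[i], df2 = tab$Df[j],
               ss_effect = tab$`Sum Sq`[i], ss_error = tab$`Sum Sq`[j],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    pull("Error: participant:movement", "movement"),
    pull("Error: participant:delay", "delay"),
    pull("Error: participant:movement:delay", "movement:delay")
  )
  out$eta_p2 <- out$ss_effect / (out$ss_effect + out$ss_error)
  rownames(out) <- NULL

  if (gg) {
    out$epsilon <- NA_real_
    out$p_gg <- out$p
    # participants x cells matrix, columns ordered movement within delay
    lv_m <- levels(d$movement); lv_d <- levels(d$delay)
    cell <- paste(as.character(d$movement), as.character(d$delay), sep = ".")
    wide <- tapply(d$mean_rt_ms, list(d$participant, cell), mean)
    cols <- as.vector(outer(lv_m, lv_d, function(m, dd) paste(m, dd, sep = ".")))
    wide <- wide[, cols, drop = FALSE]
    contr <- function(k) {   # k-1 orthonormal polynomial-free contrasts
      C <- stats::contr.helmert(k)
      qr.Q(qr(C))
    }
    Cm <- contr(length(lv_m)); Cd <- contr(length(lv_d))
    ones_m <- matrix(1 / sqrt(length(lv_m)), length(lv_m), 1)
    eff_contrasts <- list(
      delay = kronecker(Cd, ones_m),
      `movement:delay` = kronecker(Cd, Cm)
    )
    for (eff in names(eff_contrasts)) {
      M <- eff_contrasts[[eff]]
      if (ncol(M) < 2L) next
      S <- stats::cov(wide %*% M)
      eps <- sum(diag(S))^2 / (ncol(M) * sum(S * S))
      i <- match(eff, out$effect)
      out$epsilon[i] <- eps
      out$p_gg[i] <- stats::pf(out$F[i], eps * out$df1[i], eps * out$df2[i],
                               lower.tail = FALSE)
    }
  }
  out
}

#' Per-delay paired contrast of fixed vs looming
#'
#' At each delay, a paired t test across participants on the ln-scale cell
#' means (equivalently, on the log of the geometric-mean RTs), reported with
#' the ms-scale mean difference.  Facilitation is positive when looming is
#' faster (fixed minus looming).  Unadjusted p-values by default; Holm
#' adjustment available.
#'
#' @param cell_means Long data frame `participant, movement, delay_label,
#'   mean_rt_ms`, complete and balanced.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame with one row per delay: `delay_label,
#'   facilitation_ms, t, df, p`.
#' @export
per_delay_contrast <- function(cell_means, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(cell_means))
  delays <- intersect(names(tactile_delays_ms), unique(cell_means$delay_label))
  out <- do.call(rbind, lapply(delays, function(d) {
    sub <- cell_means[cell_means$delay_label == d, ]
    sub <- sub[order(sub$participant), ]
    fx <- sub$mean_rt_ms[sub$movement == "fixed"]
    lo <- sub$mean_rt_ms[sub$movement == "looming"]
    if (length(fx) != length(lo) || length(fx) < 2L)
      stop_input("incomplete design at delay %s", d)
    tt <- stats::t.test(log(fx), log(lo), paired = TRUE)
    data.frame(delay_label = d,
               facilitation_ms = mean(fx) - mean(lo),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Run the full RT analysis pipeline
#'
#' Exclusion (miss-rate rule), RT filtering, log-transformed condition
#' means, per-delay contrasts, and the two-way within-subject ANOVA, in the
#' order an analyst would run them.
#'
#' @param cohort A `cohort_sessions` data frame ([simulate_cohort()] or
#'   [read_cohort_dir()]).
#' @param filter_low,filter_high RT window bounds, ms.
#' @param exclude_rule Passed to [exclude_participants()]; `NULL` disables
#'   exclusion.
#' @param adjust P-value adjustment for the per-delay contrasts.
#' @param gg Greenhouse-Geisser columns in the ANOVA table?
#' @return Object of class `rt_analysis`: list with `miss_rates`,
#'   `exclusion`, `removed_pct`, `summary` ([condition_means()]), `anova`
#'   ([rm_anova()]), `contrasts` ([per_delay_contrast()]) and `n_analyzed`.
#' @export
analyze_sessions <- function(cohort, filter_low = 100, filter_high = 1000,
                             exclude_rule = "mean_3sd",
                             adjust = c("none", "holm"), gg = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(cohort))
  rates <- miss_rates(cohort)
  if (!is.null(exclude_rule) && length(rates) >= 2L) {
    excl <- exclude_participants(rates, rule = exclude_rule)
  } else {
    excl <- list(kept = names(rates), excluded = character(0),
                 cutoff = NA_real_, mean = mean(rates),
                 sd = stats::sd(rates))
  }
  kept <- cohort[cohort$participant %in% excl$kept, , drop = FALSE]
  filt <- filter_rts(kept, low = filter_low, high = filter_high)
  summ <- condition_means(filt$records)
  anova_tab <- rm_anova(summ$cell_means, gg = gg)
  contrasts <- per_delay_contrast(summ$cell_means, adjust = adjust)
  structure(
    list(miss_rates = rates, exclusion = excl,
         removed_pct = filt$removed_pct, summary = summ,
         anova = anova_tab, contrasts = contrasts,
         n_analyzed = length(excl$kept)),
    class = "rt_analysis"
  )
}

#' @export
print.rt_analysis <- function(x, ...) {
  cat(sprintf("<rt_analysis> %d participants analyzed (%d excluded), %.2f%% of RTs filtered\n",
              x$n_analyzed, length(x$exclusion$excluded), x$removed_pct))
  cat("\nANOVA:\n"); print(x$anova, row.names = FALSE)
  cat("\nPer-delay fixed vs looming:\n"); print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Write analysis outputs as tidy CSVs
#'
#' Writes `condition_summary.csv` (movement, delay, mean_rt_ms, sem_ms,
#' facilitation_ms), `anova.csv` and `contrasts.csv` to a directory.
#'
#' @param analysis An [analyze_sessions()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_analysis_csvs <- function(analysis, dir) {
  stopifnot(inherits(analysis, "rt_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grp <- analysis$summary$group
  grp$facilitation_ms <- analysis$summary$facilitation$facilitation_ms[
    match(grp$delay_label, analysis$summary$facilitation$delay_label)]
  paths <- c(
    condition_summary = file.path(dir, "condition_summary.csv"),
    anova = file.path(dir, "anova.csv"),
    contrasts = file.path(dir, "contrasts.csv")
  )
  utils::write.csv(grp, paths[["condition_summary"]], row.names = FALSE)
  utils::write.csv(analysis$anova, paths[["anova"]], row.names = FALSE)
  utils::write.csv(analysis$contrasts, paths[["contrasts"]], row.names = FALSE)
  invisible(unname(paths))
}
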