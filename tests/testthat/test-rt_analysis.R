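test_that("miss-rate exclusion removes only outlying participants", {
  # zero spread: nobody excluded
  even <- stats::setNames(rep(1.5, 10), sprintf("P%02d", 1:10))
  res <- exclude_participants(even)
  expect_length(res$excluded, 0L)

  # one participant at 9.0% against a low-miss sample: excluded by mean + 3 SD
  rates <- stats::setNames(c(rep(1, 19), 9), sprintf("P%02d", 1:20))
  res2 <- exclude_participants(rates)
  expect_equal(res2$excluded, "P20")
  expect_equal(res2$cutoff, mean(rates) + 3 * sd(rates))
  expect_gt(9, res2$cutoff)

  # single pass: the rule is NOT re-applied after exclusion
  # (re-screening the 19 survivors at their own mean + 3 SD would keep all,
  # but a borderline participant must not be re-judged on the reduced sample)
  rates3 <- stats::setNames(c(rep(1, 18), 4.2, 9), sprintf("P%02d", 1:20))
  res3 <- exclude_participants(rates3)
  expect_equal(res3$excluded, "P20")  # 4.2 < cutoff computed on full sample

  # pluggable rule
  res4 <- exclude_participants(rates, rule = function(r) r < 5)
  expect_equal(res4$excluded, "P20")

  expect_error(exclude_participants(c(a = 1)), "at least 2")
})

test_that("RT filtering keeps the closed [low, high] window", {
  rec <- data.frame(rt_ms = c(99, 100, 500, 1000, 1001))
  out <- filter_rts(rec)
  expect_equal(out$records$rt_ms, c(100, 500, 1000))  # boundaries kept
  expect_equal(out$removed_pct, 40)

  clean <- data.frame(rt_ms = c(150, 300, 999))
  expect_equal(filter_rts(clean)$removed_pct, 0)

  # trials without an RT pass through and are not counted
  mixed <- data.frame(rt_ms = c(NA, 50, 500))
  outm <- filter_rts(mixed)
  expect_equal(outm$removed_pct, 50)
  expect_equal(nrow(outm$records), 2L)

  expect_warning(out0 <- filter_rts(data.frame(rt_ms = NA_real_)), "no RT")
  expect_equal(out0$removed_pct, 0)
  expect_error(filter_rts(rec, low = 500, high = 100), "exceed")
})

test_that("condition means are back-transformed log means (geometric means)", {
  # identical RTs: the back-transformed mean is that RT
  df1 <- data.frame(participant = "P1",
                    movement = rep(c("fixed", "looming"), each = 6),
                    delay_label = rep(paste0("T", 1:6), 2),
                    rt_ms = 350)
  cm1 <- condition_means(df1)
  expect_equal(cm1$cell_means$mean_rt_ms, rep(350, 12))

  # cell (100, 400): geometric mean 200, not the arithmetic 250
  df2 <- rbind(df1,
               data.frame(participant = "P1", movement = "fixed",
                          delay_label = "T1", rt_ms = c(100, 400)))
  df2 <- df2[!(df2$rt_ms == 350 & df2$movement == "fixed" &
                 df2$delay_label == "T1"), ]
  cm2 <- condition_means(df2)
  got <- cm2$cell_means
  expect_equal(got$mean_rt_ms[got$movement == "fixed" &
                                got$delay_label == "T1"], 200)

  # an empty cell is an error naming participant and cell
  df3 <- df1[!(df1$movement == "looming" & df1$delay_label == "T4"), ]
  expect_error(condition_means(df3), "P1.*looming.*T4")
})

test_that("condition means are invariant to trial order within a cell", {
  sched <- generate_schedule(n_blocks = 2, seed = 1)
  cohort <- simulate_cohort(sched, cohort_params(n_participants = 4,
                                                 miss_prob = 0, seed = 7))
  shuffled <- cohort[withr::with_seed(1, sample(nrow(cohort))), ]
  a <- condition_means(cohort)
  b <- condition_means(shuffled)
  expect_equal(a$group, b$group)
  expect_equal(a$facilitation, b$facilitation)
})

test_that("the repeated-measures ANOVA has the right df structure", {
  df <- random_cell_means(18, delays = paste0("T", 1:6), seed = 2)
  out <- rm_anova(df)
  expect_equal(out$df1[out$effect == "movement"], 1)
  expect_equal(out$df2[out$effect == "movement"], 17)
  expect_equal(out$df1[out$effect == "delay"], 5)
  expect_equal(out$df2[out$effect == "delay"], 85)
  expect_equal(out$df1[out$effect == "movement:delay"], 5)
  expect_equal(out$df2[out$effect == "movement:delay"], 85)
  expect_true(all(out$eta_p2 >= 0 & out$eta_p2 <= 1))
})

test_that("ANOVA effects vanish when all cell means are equal", {
  df <- random_cell_means(5, delays = paste0("T", 1:3))
  df$mean_rt_ms <- 400
  out <- rm_anova(df)
  expect_equal(out$ss_effect, rep(0, 3), tolerance = 1e-10)
})

test_that("the ANOVA matches a brute-force SS decomposition on small designs", {
  cases <- list(
    list(n = 3, delays = c("T1", "T2")),
    list(n = 4, delays = c("T1", "T2")),
    list(n = 3, delays = c("T1", "T2", "T3")),
    list(n = 4, delays = c("T1", "T2", "T3"))
  )
  for (i in seq_along(cases)) {
    df <- random_cell_means(cases[[i]]$n, delays = cases[[i]]$delays,
                            seed = 50 + i)
    got <- rm_anova(df)
    want <- brute_force_rm_anova(df)
    for (pair in list(c("movement", "movement"), c("delay", "delay"),
                      c("movement:delay", "interaction"))) {
      row <- got[got$effect == pair[1], ]
      ref <- want[[pair[2]]]
      expect_equal(row$ss_effect, ref$ss, tolerance = 1e-8)
      expect_equal(row$ss_error, ref$ss_err, tolerance = 1e-8)
      expect_equal(row$F, ref$F, tolerance = 1e-8)
      expect_equal(row$df1, ref$df1)
      expect_equal(row$df2, ref$df2)
    }
  }
})

test_that("Greenhouse-Geisser epsilon is sane and leaves 1-df effects alone", {
  df <- random_cell_means(10, delays = paste0("T", 1:6), seed = 3)
  # add a real delay effect so the corrected test is in its upper tail
  df$mean_rt_ms <- df$mean_rt_ms - 15 * as.integer(factor(df$delay_label))
  out <- rm_anova(df, gg = TRUE)
  eps <- out$epsilon[out$effect == "delay"]
  expect_gte(eps, 1 / 5)   # lower bound 1/(k-1)
  expect_lte(eps, 1 + 1e-9)
  expect_true(is.na(out$epsilon[out$effect == "movement"]))
  expect_gte(out$p_gg[out$effect == "delay"], out$p[out$effect == "delay"])
})

test_that("unbalanced designs are rejected", {
  df <- random_cell_means(4, delays = c("T1", "T2"))
  expect_error(rm_anova(df[-1, ]), "balanced")
})

test_that("per-delay contrasts use the documented sign convention", {
  # fixed slower than looming by construction: facilitation positive
  df <- random_cell_means(10, delays = c("T1", "T2"), seed = 4)
  df$mean_rt_ms <- 400 + withr::with_seed(4, rnorm(nrow(df), 0, 5))
  df$mean_rt_ms[df$movement == "fixed"] <-
    df$mean_rt_ms[df$movement == "fixed"] + 30
  out <- per_delay_contrast(df)
  expect_true(all(out$facilitation_ms > 0))
  expect_true(all(out$p < 0.01))
  expect_equal(out$df, rep(9, 2))

  # zero injected effect: differences centred on 0
  df0 <- random_cell_means(40, delays = c("T1", "T2"), seed = 5)
  out0 <- per_delay_contrast(df0)
  expect_lt(max(abs(out0$facilitation_ms)), 30)
  expect_true(all(out0$p > 1e-4))

  # Holm adjustment never lowers p-values
  outh <- per_delay_contrast(df0, adjust = "holm")
  expect_true(all(outh$p >= out0$p))
})

test_that("the full pipeline excludes, filters and summarizes", {
  # n = 16 so a single outlier can clear the mean + 3 SD bar (the largest
  # attainable z in a sample of n is (n-1)/sqrt(n), which only exceeds 3 for
  # n >= 11)
  sched <- generate_schedule(seed = 1)
  cohort <- simulate_cohort(sched, cohort_params(n_participants = 16, seed = 11))
  # make one participant miss 15% of experimental trials
  bad <- cohort$participant == "P16" & !cohort$is_catch
  idx <- which(bad)[seq_len(round(0.15 * sum(bad)))]
  cohort$rt_ms[idx] <- NA
  cohort$response[idx] <- "miss"

  res <- analyze_sessions(cohort)
  expect_equal(res$exclusion$excluded, "P16")
  expect_equal(res$n_analyzed, 15L)
  expect_equal(nrow(res$summary$group), 12L)
  expect_equal(nrow(res$anova), 3L)
  expect_equal(nrow(res$contrasts), 6L)

  # determinism: identical inputs give identical tables
  res2 <- analyze_sessions(cohort)
  expect_identical(res$summary$group, res2$summary$group)
  expect_identical(res$anova, res2$anova)
})
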