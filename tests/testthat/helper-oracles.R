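# Independent oracles and shared fixtures for the test suite.

# Naive sample-by-sample EWMA recursion, written independently of the
# package's filter-based implementation.
naive_ewma <- function(x, alpha) {
  y <- numeric(length(x))
  for (n in seq_along(x)[-1]) {
    y[n] <- abs(x[n - 1] - x[n]) * (1 - alpha) + alpha * y[n - 1]
  }
  y
}

# Brute-force two-way within-subject ANOVA from definitional sums of
# squares, for a long data frame with columns participant, movement,
# delay_label, mean_rt_ms (complete balanced design).
brute_force_rm_anova <- function(df) {
  y <- df$mean_rt_ms
  A <- factor(df$movement)         # a levels
  B <- factor(df$delay_label)      # b levels
  S <- factor(df$participant)      # n subjects
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  grand <- mean(y)
  m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean); m_s <- tapply(y, S, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_as <- tapply(y, list(A, S), mean)
  m_bs <- tapply(y, list(B, S), mean)

  ss_A <- b * n * sum((m_a - grand)^2)
  ss_B <- a * n * sum((m_b - grand)^2)
  ss_AB <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_AS <- b * sum((m_as - outer(m_a, rep(1, n)) -
                      outer(rep(1, a), m_s) + grand)^2)
  ss_BS <- a * sum((m_bs - outer(m_b, rep(1, n)) -
                      outer(rep(1, b), m_s) + grand)^2)
  resid <- vapply(seq_along(y), function(i) {
    ai <- as.integer(A[i]); bi <- as.integer(B[i]); si <- as.integer(S[i])
    y[i] - m_ab[ai, bi] - m_as[ai, si] - m_bs[bi, si] +
      m_a[ai] + m_b[bi] + m_s[si] - grand
  }, numeric(1))
  ss_ABS <- sum(resid^2)

  f <- function(ss_eff, df_eff, ss_err, df_err) {
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  list(
    movement = list(ss = ss_A, df1 = a - 1, ss_err = ss_AS,
                    df2 = (a - 1) * (n - 1),
                    F = f(ss_A, a - 1, ss_AS, (a - 1) * (n - 1))),
    delay = list(ss = ss_B, df1 = b - 1, ss_err = ss_BS,
                 df2 = (b - 1) * (n - 1),
                 F = f(ss_B, b - 1, ss_BS, (b - 1) * (n - 1))),
    interaction = list(ss = ss_AB, df1 = (a - 1) * (b - 1), ss_err = ss_ABS,
                       df2 = (a - 1) * (b - 1) * (n - 1),
                       F = f(ss_AB, (a - 1) * (b - 1), ss_ABS,
                             (a - 1) * (b - 1) * (n - 1)))
  )
}

# A quiet 500 Hz / 120 Hz device with no latency or noise.
noiseless_profile <- function(accel_rate_hz = 500, touch_rate_hz = 120) {
  device_profile("noiseless", accel_rate_hz = accel_rate_hz,
                 touch_rate_hz = touch_rate_hz, accel_noise_sd = 0)
}

# Random long-format cell means for a complete a x b x n design.
random_cell_means <- function(n_subj, movements = c("fixed", "looming"),
                              delays = c("T1", "T2"), seed = 1) {
  df <- expand.grid(participant = sprintf("S%02d", seq_len(n_subj)),
                    movement = movements, delay_label = delays,
                    stringsAsFactors = FALSE)
  df$mean_rt_ms <- withr::with_seed(seed, stats::rnorm(nrow(df), 400, 40))
  df
}
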