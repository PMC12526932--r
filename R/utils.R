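# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_input("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stop_input("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stop_input("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# Times in session/bench CSVs are stored to 0.001 ms; rounding at generation
# time makes write -> read an exact identity.
round_ms <- function(x) round(x, 3L)

# Sample (n-1) standard deviation, NA-safe length check.
sample_sd <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}
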