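# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; if `seed`
# is NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage child seeds spawned from one master seed.
# stage is a character tag; the rule is a fixed linear-congruential mix of
# the master seed and a polynomial hash of the tag, reduced mod 2^31 - 1.
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807 + 12345) %% 2147483647)
}

# Raised-cosine on/off ramp envelope of length n samples (0 -> 1).
raised_cosine <- function(n) {
  if (n <= 0) return(numeric(0))
  0.5 * (1 - cos(pi * (seq_len(n) - 0.5) / n))
}

# Sample count of a half-open window [t0, t1) in ms at rate_hz.
window_n_samples <- function(window_ms, rate_hz) {
  as.integer(round((window_ms[2] - window_ms[1]) * rate_hz / 1000))
}

# Sample times (ms) of an epoch with half-open window starting at t0_ms.
epoch_times_ms <- function(t0_ms, n, rate_hz) {
  t0_ms + (seq_len(n) - 1L) * 1000 / rate_hz
}

# Logical selector for samples falling in half-open [w0, w1) ms.
in_window <- function(times_ms, window_ms) {
  times_ms >= window_ms[1] & times_ms < window_ms[2]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
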