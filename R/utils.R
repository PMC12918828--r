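# Internal helpers shared across modules.

# Evaluate a function with a locally seeded RNG, restoring global RNG state.
# seed = NULL leaves the RNG alone (caller inherits ambient randomness).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Three-point parabolic refinement of a grid maximum. i is the index of the
# discrete argmax of y; returns the interpolated abscissa (clamped to the
# neighbouring grid interval) and interpolated ordinate.
parabolic_refine <- function(x, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) {
    return(list(x = x[i], y = y[i]))
  }
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * max(1, abs(y1))) {
    return(list(x = x[i], y = y[i]))
  }
  # offset in units of the (locally uniform) grid step
  delta <- 0.5 * (y0 - y2) / denom
  delta <- max(-1, min(1, delta))
  h <- (x[i + 1L] - x[i - 1L]) / 2
  list(x = x[i] + delta * h, y = y1 - 0.25 * (y0 - y2) * delta)
}

# Deterministic 32-bit-safe hash combining a base seed with an index/value,
# for per-wavelength substream seeds. All arithmetic stays below 2^53 so it
# is exact in doubles; result lies in [0, 2^31 - 2].
derive_seed <- function(seed, key) {
  a <- (seed %% 2147483647) * 48271 %% 2147483647
  b <- (round(key * 8192) %% 2147483647) * 69621 %% 2147483647
  s <- (a + b + 1) %% 2147483646
  s + 1
}

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
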