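# Internal helpers shared across modules.

# Deterministic sub-seed derivation: all randomness in a run flows from one
# master seed; each named component gets its own reproducible stream.
deriveSeed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# GCaMP-like single-exponential decay kernel sampled at frameRate, unit peak.
calciumKernel <- function(tau, frameRate, durationS = 6 * tau) {
  t <- seq(0, durationS, by = 1 / frameRate)
  exp(-t / tau)
}

# Longest run of TRUE and whether a qualifying run starts within the first
# `withinFirst` positions of `x`.
runStartsWithin <- function(x, minLen, withinFirst) {
  if (!any(x)) return(FALSE)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= minLen & starts <= withinFirst
  any(ok)
}

# Row-wise minima of a small matrix without per-row function calls.
rowMins <- function(m) {
  if (ncol(m) == 1L) return(as.vector(m))
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

# Linear pixel index (column-major, as R stores matrices) <-> (row, col).
pixelIndex <- function(row, col, nr) (col - 1L) * nr + row

# Lexicographic (row, col) key used for deterministic tie-breaking.
lexKey <- function(row, col, nc) (row - 1) * nc + col

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
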