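# Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so simulations are reproducible without
# clobbering the session RNG.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed, kept within 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

# Multiplicative lognormal noise factors with mean 1 and coefficient of
# variation cv (cv = 0 returns exact ones).
lognormNoise <- function(n, cv) {
  if (cv < 0) stop("noise CV must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# Rolling minimum by brute force over a centred window of `width` samples.
# Traces are a few thousand points, so O(n * width) is fine.
rollingMin <- function(x, width) {
  n <- length(x)
  if (width <= 1L) return(x)
  half <- width %/% 2L
  vapply(seq_len(n), function(i) {
    min(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

rollingMax <- function(x, width) {
  n <- length(x)
  if (width <= 1L) return(x)
  half <- width %/% 2L
  vapply(seq_len(n), function(i) {
    max(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Centred moving average with an odd window; edges use the available samples.
movingAverage <- function(x, width) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

# Piecewise-linear interpolation through (x0, y0) with linear extrapolation
# beyond the first/last knot (stats::approx rule=2 would clamp instead).
linInterp <- function(x0, y0, x) {
  stopifnot(length(x0) >= 2L)
  y <- stats::approx(x0, y0, xout = x, ties = "ordered")$y
  lo <- x < x0[1L]
  hi <- x > x0[length(x0)]
  if (any(lo)) {
    s <- (y0[2L] - y0[1L]) / (x0[2L] - x0[1L])
    y[lo] <- y0[1L] + s * (x[lo] - x0[1L])
  }
  if (any(hi)) {
    m <- length(x0)
    s <- (y0[m] - y0[m - 1L]) / (x0[m] - x0[m - 1L])
    y[hi] <- y0[m] + s * (x[hi] - x0[m])
  }
  y
}

# Coerce a sequence argument to an upper-case character RNA string, validating
# the alphabet. Accepts character, RNAString, or DNAString (T -> U).
asRnaChar <- function(sequence) {
  if (is(sequence, "XString")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single string or an RNAString", call. = FALSE)
  s <- chartr("t", "u", toupper(sequence))
  s <- chartr("T", "U", s)
  if (nchar(s) == 0L) stop("'sequence' must be non-empty", call. = FALSE)
  if (grepl("[^ACGU]", s))
    stop("sequence contains characters outside {A,C,G,U}", call. = FALSE)
  s
}
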