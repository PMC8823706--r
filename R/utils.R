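# Shared numeric helpers: circular arithmetic, sliding means, rank AUC.

# wrap angle (deg) into [0, 360)
wrap360 <- function(x) x %% 360

# signed circular difference a - b in (-180, 180]
circDiff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# unwrap a wrapped heading series (deg) into a continuous series
unwrapDeg <- function(x) {
  if (length(x) < 2L) return(x)
  x[1L] + c(0, cumsum(circDiff(x[-1L], x[-length(x)])))
}

# centered sliding mean, edges shrunk to available samples
slideMean <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L || length(x) < 2L) return(x)
  half <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# circular sliding mean of a heading series via unit vectors (deg)
slideMeanCircular <- function(x, width) {
  c_ <- slideMean(cos(x * pi / 180), width)
  s_ <- slideMean(sin(x * pi / 180), width)
  wrap360(atan2(s_, c_) * 180 / pi)
}

# mid-rank AUC for pos > neg (Mann-Whitney); ties get 0.5 credit
rankAUC <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  stopifnot(n1 > 0L, n2 > 0L)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Pearson r that tolerates zero-variance input (returns NA, no warning)
safeCor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y)
}

# child seed in [0, 2^31): deterministic derivation from a user seed
childSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

# spike counts per frame interval; frames at t with spacing dt
countsPerFrame <- function(times, frameStart, dt, nFrames) {
  idx <- floor((times - frameStart) / dt) + 1
  idx <- idx[idx >= 1 & idx <= nFrames]
  tabulate(idx, nbins = nFrames)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
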