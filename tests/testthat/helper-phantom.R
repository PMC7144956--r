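# Shared fixtures: phantoms are generated in code, never stored.

# Full-resolution spec matching the reference study conditions.
fullSpec <- function(...) phantomSpec(...)

# Smaller, faster phantom for structural tests: same 256 mm field of view
# at 2 mm spacing.
smallSpec <- function(...) {
  phantomSpec(imageSize = c(128L, 128L), spacing = 2, ...)
}

# Independent brute-force Otsu oracle: scans every cut point, computing
# class weights and means directly from the raw counts (no cumulative
# sums), with ties kept at the lowest cut.
bruteOtsu <- function(breaks, counts) {
  nb <- length(counts)
  mids <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  best <- -1  # bcv is nonnegative
  bestK <- NA_integer_
  for (k in seq_len(nb - 1)) {
    lo <- seq_len(k)
    hi <- (k + 1):nb
    n0 <- sum(counts[lo]); n1 <- sum(counts[hi])
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / (n0 + n1); w1 <- 1 - w0
    mu0 <- sum(counts[lo] * mids[lo]) / n0
    mu1 <- sum(counts[hi] * mids[hi]) / n1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    # strictly better beyond float noise: ties keep the lowest cut
    if (bcv > best + abs(best) * 1e-10) {
      best <- bcv
      bestK <- k
    }
  }
  breaks[bestK + 1]
}

randomHistogram <- function(maxBins = 64L) {
  nb <- sample(2:maxBins, 1)
  counts <- stats::rpois(nb, lambda = sample(1:20, 1))
  while (sum(counts > 0) < 2) counts <- stats::rpois(nb, 5)
  lo <- stats::runif(1, -50, 50)
  w <- stats::runif(1, 0.1, 10)
  new("HistogramModel", breaks = lo + w * (0:nb),
      counts = as.numeric(counts), n = as.integer(sum(counts)))
}
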