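# Independent oracles used across tests: deliberately naive implementations
# that share no code with the package internals they check.

# Pixel-by-pixel threshold comparison (explicit double loop).
bruteForceFatCount <- function(slice, roiSlice, threshold) {
  count <- 0L
  for (i in seq_len(nrow(slice))) {
    for (j in seq_len(ncol(slice))) {
      if (roiSlice[i, j] && slice[i, j] >= threshold) count <- count + 1L
    }
  }
  count
}

# Through-origin slope by grid search over the residual sum of squares.
gridSearchSlope <- function(p, v, lower = 0, upper = 1, step = 1e-6) {
  grid <- seq(lower, upper, by = step)
  sse <- sum(p^2) - 2 * grid * sum(p * v) + grid^2 * sum(v^2)
  grid[which.min(sse)]
}

# Local maxima of a vector by direct enumeration (no plateau subtlety:
# callers pass strictly varying vectors).
bruteForceLocalMaxima <- function(y) {
  n <- length(y)
  which(vapply(seq_len(n), function(i) {
    left <- if (i == 1L) TRUE else y[i - 1L] < y[i]
    right <- if (i == n) TRUE else y[i + 1L] < y[i]
    left && right
  }, logical(1)))
}

# A small toy slice with a reproducible bimodal SI pattern.
makeToySlice <- function(nr = 16, nc = 16, seed = 1) {
  set.seed(seed)
  fat <- matrix(runif(nr * nc) < 0.4, nr, nc)
  si <- matrix(rnorm(nr * nc, 0.25, 0.06), nr, nc)
  si[fat] <- rnorm(sum(fat), 0.75, 0.06)
  roi <- matrix(FALSE, nr, nc)
  roi[2:(nr - 1), 2:(nc - 1)] <- TRUE
  list(slice = si, roi = roi)
}
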