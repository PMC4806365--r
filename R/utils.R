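# Internal helpers shared across modules.

# Canonical landmark order, most caudal first.  Ties in sigma-based ranking
# break toward the more caudal landmark, i.e. earlier in this vector.
LANDMARK_ORDER <- c("PF", "FH", "L5S1", "UM", "L4L5", "L3L4", "L2L3", "L1L2", "D")

# Landmarks usable as prediction reference levels (PF/D delimit the volume).
REFERENCE_LANDMARKS <- c("L1L2", "L2L3", "L3L4", "L4L5", "L5S1", "UM", "FH")

vatCondition <- function(class, message, call = sys.call(-1)) {
  structure(
    class = c(class, "vatmriError", "error", "condition"),
    list(message = message, call = call)
  )
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state.  All generators take mandatory seeds and route through this.
withSeed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    stop("a finite integer 'seed' is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Centered moving average with truncated windows at the edges (window
# shrinks near the boundary instead of padding), so edge peaks survive.
movingAverage <- function(x, k = 5L) {
  n <- length(x)
  half <- k %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Local maxima of a numeric vector with plateau handling.  Returns a data
# frame with one row per maximum: the run's start/end index and height.
# Edge runs count as maxima when they exceed their single neighbour.
localMaxima <- function(y) {
  r <- rle(y)
  nruns <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  isMax <- logical(nruns)
  for (i in seq_len(nruns)) {
    leftOK <- i == 1L || r$values[i - 1L] < r$values[i]
    rightOK <- i == nruns || r$values[i + 1L] < r$values[i]
    isMax[i] <- leftOK && rightOK
  }
  data.frame(start = starts[isMax], end = ends[isMax],
             height = r$values[isMax])
}

# Topographic prominence of each local maximum: height minus the key col,
# the higher of the two minima separating the peak from higher terrain on
# either side.  The global maximum's prominence is height - min(y).
# Equal-height summits: the leftmost acts as parent (the left walk treats
# equal terrain as higher), so ties cannot all claim full prominence.
peakProminence <- function(peaks, y) {
  n <- length(y)
  vapply(seq_len(nrow(peaks)), function(i) {
    h <- peaks$height[i]
    keyL <- keyR <- -Inf
    j <- peaks$start[i] - 1L
    runMin <- h
    while (j >= 1L) {
      if (y[j] >= h) { keyL <- runMin; break }
      runMin <- min(runMin, y[j])
      j <- j - 1L
    }
    j <- peaks$end[i] + 1L
    runMin <- h
    while (j <= n) {
      if (y[j] > h) { keyR <- runMin; break }
      runMin <- min(runMin, y[j])
      j <- j + 1L
    }
    key <- max(keyL, keyR)
    if (!is.finite(key)) key <- min(y)   # global maximum
    h - key
  }, numeric(1))
}

# Skew-normal shaped axial profile, parameterised by its mode and peak
# height: location/scale are solved so the curve peaks at `offset` with
# value 1 before scaling.  Shape alpha = 0 gives a Gaussian.
snMode <- function(alpha) {
  if (abs(alpha) < 1e-12) return(0)
  stats::optimize(function(t) -2 * stats::dnorm(t) * stats::pnorm(alpha * t),
                  c(-5, 5))$minimum
}

snShape <- function(h, offsetCm, widthCm, alpha) {
  m0 <- snMode(alpha)
  peak <- 2 * stats::dnorm(m0) * stats::pnorm(alpha * m0)
  z <- (h - (offsetCm - widthCm * m0)) / widthCm
  2 * stats::dnorm(z) * stats::pnorm(alpha * z) / peak
}
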