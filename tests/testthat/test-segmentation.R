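test_that("histogram binning counts every ROI pixel exactly once", {
  sl <- matrix(c(0.1, 0.1, 0.9, 0.9), 2)
  h <- sliceHistogram(sl, matrix(TRUE, 2, 2), nBins = 10, limits = c(0, 1))
  expect_identical(sum(h@counts), 4L)
  expect_identical(h@counts[2], 2L)   # [0.1, 0.2)
  expect_identical(h@counts[10], 2L)  # [0.9, 1.0]
  expect_identical(sum(h@counts[-c(2, 10)]), 0L)

  # random values: counts always sum to ROI size
  set.seed(11)
  for (i in 1:5) {
    toy <- makeToySlice(seed = i)
    h <- sliceHistogram(toy$slice, toy$roi)
    expect_identical(sum(h@counts), sum(toy$roi))
  }
})

test_that("constant-intensity ROI occupies a single bin", {
  sl <- matrix(0.42, 4, 4)
  h <- sliceHistogram(sl, matrix(TRUE, 4, 4), nBins = 16)
  expect_identical(sum(h@counts > 0L), 1L)
  expect_identical(max(h@counts), 16L)
})

test_that("empty ROI signals an empty-slice condition", {
  expect_error(
    sliceHistogram(matrix(1, 3, 3), matrix(FALSE, 3, 3)),
    class = "emptySlice")
})

test_that("smoothed histogram of a separable slice has exactly two maxima", {
  # brute-force enumeration of local maxima on the smoothed counts
  set.seed(2)
  v <- c(rnorm(600, 0.2, 0.04), rnorm(400, 0.8, 0.04))
  sl <- matrix(v, 25, 40)
  h <- sliceHistogram(sl, matrix(TRUE, 25, 40), nBins = 32)
  peaks <- bruteForceLocalMaxima(h@smoothedCounts)
  # collapse adjacent plateau indices into runs
  runs <- sum(diff(c(-10, peaks)) > 1)
  expect_identical(runs, 2L)
})

test_that("peak detection applies the halfway rule", {
  # spikes at 0.2 and 0.8: local minimum at 0.5, threshold (0.5+0.8)/2
  sl <- matrix(rep(c(0.2, 0.8), c(240, 160)), 20, 20)
  h <- sliceHistogram(sl, matrix(TRUE, 20, 20))
  m <- detectPeaks(h)
  bw <- diff(h@binEdges[1:2])
  expect_lt(abs(m@leanPeakSI - 0.2), bw)
  expect_lt(abs(m@fatPeakSI - 0.8), bw)
  expect_lt(abs(m@localMinSI - 0.5), bw)
  expect_lt(abs(m@thresholdSI - 0.65), bw)
  expect_equal(m@thresholdSI, (m@localMinSI + m@fatPeakSI) / 2)
})

test_that("symmetric bimodal mixture puts the local minimum at the midpoint", {
  # equal weights, equal SDs: analytic argmin of the mixture density is the
  # midpoint of the two component means
  set.seed(3)
  v <- c(rnorm(4000, 0.3, 0.07), rnorm(4000, 0.7, 0.07))
  sl <- matrix(v, 80, 100)
  h <- sliceHistogram(sl, matrix(TRUE, 80, 100), nBins = 64)
  m <- detectPeaks(h)
  bw <- diff(h@binEdges[1:2])
  expect_lt(abs(m@localMinSI - 0.5), bw + 0.01)
})

test_that("unimodal histograms signal no-bimodal-structure", {
  set.seed(4)
  sl <- matrix(rnorm(400, 0.5, 0.05), 20, 20)
  h <- sliceHistogram(sl, matrix(TRUE, 20, 20), nBins = 16)
  expect_error(detectPeaks(h), class = "noBimodalStructure")
})

test_that("segmentSlice agrees with brute-force pixel comparison", {
  model <- new("ThresholdModel", leanPeakSI = 0.2, localMinSI = 0.5,
               fatPeakSI = 0.8, thresholdSI = 0.65,
               manualOverride = NA_real_)
  for (s in 1:20) {
    toy <- makeToySlice(seed = s)
    mask <- segmentSlice(toy$slice, toy$roi, model)
    expect_identical(sum(mask), bruteForceFatCount(toy$slice, toy$roi, 0.65))
    expect_false(any(mask & !toy$roi))  # mask subset of ROI
  }
})

test_that("threshold extremes give empty and saturating masks", {
  toy <- makeToySlice()
  mk <- function(thr) new("ThresholdModel", leanPeakSI = NA_real_,
                          localMinSI = NA_real_, fatPeakSI = NA_real_,
                          thresholdSI = NA_real_, manualOverride = thr)
  expect_false(any(segmentSlice(toy$slice, toy$roi,
                                mk(max(toy$slice) + 1))))
  expect_identical(segmentSlice(toy$slice, toy$roi,
                                mk(min(toy$slice))), toy$roi)
})

test_that("raising the threshold never increases the mask pixel count", {
  toy <- makeToySlice(seed = 7)
  thresholds <- seq(0, 1, by = 0.05)
  counts <- vapply(thresholds, function(t) {
    m <- new("ThresholdModel", leanPeakSI = NA_real_, localMinSI = NA_real_,
             fatPeakSI = NA_real_, thresholdSI = NA_real_,
             manualOverride = t)
    sum(segmentSlice(toy$slice, toy$roi, m))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentStack applies overrides per slice and logs them", {
  ph <- generatePhantom(phantomSpec(nSlices = 21, matrixSize = 64,
                                    pixelSpacingMm = 6.6, seed = 5))
  seg <- segmentStack(ph@image, roiMask(ph))
  ov <- c("3" = 0.9)
  seg2 <- segmentStack(ph@image, roiMask(ph), overrides = ov)
  expect_equal(effectiveThreshold(seg2$models[[3]]), 0.9)
  # only slice 3 changes; others keep their default thresholds
  for (k in seq_len(nSlices(ph@image))[-3]) {
    expect_equal(effectiveThreshold(seg2$models[[k]]),
                 effectiveThreshold(seg$models[[k]]))
  }
  expect_true(any(seg2$log$event == "manual-override" & seg2$log$slice == 3))
  # idempotence: identical inputs give identical masks
  seg3 <- segmentStack(ph@image, roiMask(ph))
  expect_identical(seg$mask, seg3$mask)
})

test_that("slices without bimodal structure require an override", {
  # constant intensities: a single occupied bin, no bimodal structure
  arr <- array(0.5, c(16, 16, 3))
  roi <- array(TRUE, c(16, 16, 3))
  stack <- imageStack(arr, 2, 10, 0.5)
  expect_error(segmentStack(stack, roi), class = "noBimodalStructure")
  ov <- structure(rep(0.6, 3), names = as.character(1:3))
  seg <- segmentStack(stack, roi, overrides = ov)
  expect_identical(sort(unique(seg$log$event)),
                   c("manual-override", "no-bimodal-structure"))
})

test_that("empty-ROI slices give empty mask slices and a null model", {
  ph <- generatePhantom(phantomSpec(nSlices = 21, matrixSize = 64,
                                    pixelSpacingMm = 6.6, seed = 9))
  roi <- roiMask(ph)
  roi[, , 2] <- FALSE
  seg <- segmentStack(ph@image, roi)
  expect_false(any(seg$mask[, , 2]))
  expect_null(seg$models[[2]])
  expect_true(any(seg$log$event == "empty-slice" & seg$log$slice == 2))
})
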