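#' Construct an ImageStack
#'
#' @param slices 3-D numeric array \code{[x, y, slice]}; slice 1 is the most
#'   caudal slice and indices increase cranially.
#' @param pixelSpacingMm isotropic in-plane pixel spacing in mm.
#' @param sliceThicknessMm nominal slice thickness in mm.
#' @param intersliceGapMm gap between adjacent slices in mm.
#' @return An [ImageStack-class] object.
#' @examples
#' st <- imageStack(array(runif(4 * 4 * 3), c(4, 4, 3)),
#'                  pixelSpacingMm = 2, sliceThicknessMm = 10,
#'                  intersliceGapMm = 0.5)
#' nSlices(st)
#' @export
imageStack <- function(slices, pixelSpacingMm, sliceThicknessMm,
                       intersliceGapMm = 0) {
  new("ImageStack",
      slices = slices,
      pixelSpacing = as.numeric(pixelSpacingMm),
      sliceThickness = as.numeric(sliceThicknessMm),
      intersliceGap = as.numeric(intersliceGapMm))
}

#' Axial extent covered by a stack
#'
#' Number of slices times the effective slice thickness, in cm.  A stack of
#' 50 slices of 10 mm thickness with a 0.5 mm gap covers 52.5 cm.
#'
#' @param stack an [ImageStack-class].
#' @return Axial extent in cm.
#' @export
axialExtent <- function(stack) {
  nSlices(stack) *
    effectiveSliceThickness(stack@sliceThickness, stack@intersliceGap)
}

#' Signal-intensity histogram of one slice's ROI
#'
#' Bins the signal intensities of the ROI pixels of a single axial slice.
#' By default 256 bins span the ROI's min-max SI range; a fixed range can
#' be supplied instead.  Bins are left-closed, the last bin closed on both
#' sides, so every ROI pixel is counted exactly once.  A 5-bin centered
#' moving average (truncated at the edges) provides the smoothed counts
#' that [detectPeaks()] operates on.
#'
#' @param slice 2-D numeric matrix of signal intensities.
#' @param roiSlice logical matrix of the same shape: the abdominal ROI.
#' @param nBins number of histogram bins (>= 8); default 256.
#' @param limits optional length-2 numeric range for the bins; default is
#'   the ROI min-max.  A constant-intensity ROI falls in a single bin.
#' @param smoothK width of the moving-average smoothing window (bins).
#' @return A [SliceHistogram-class].
#' @examples
#' sl <- matrix(c(0.1, 0.1, 0.9, 0.9), 2)
#' h <- sliceHistogram(sl, matrix(TRUE, 2, 2), nBins = 10, limits = c(0, 1))
#' sum(h@counts)  # 4
#' @export
sliceHistogram <- function(slice, roiSlice, nBins = 256L, limits = NULL,
                           smoothK = 5L) {
  stopifnot(identical(dim(slice), dim(roiSlice)))
  if (nBins < 8L) stop("'nBins' must be at least 8")
  vals <- slice[roiSlice]
  if (length(vals) == 0L)
    stop(vatCondition("emptySlice", "slice has an empty ROI"))
  if (is.null(limits)) limits <- range(vals)
  if (diff(limits) <= 0) {
    # degenerate (constant SI): a token range so the single bin is well formed
    limits <- limits + c(-0.5, 0.5)
  }
  edges <- seq(limits[1], limits[2], length.out = nBins + 1L)
  idx <- findInterval(vals, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nBins)
  counts <- tabulate(idx, nbins = nBins)
  new("SliceHistogram",
      binEdges = edges,
      counts = as.integer(counts),
      smoothedCounts = movingAverage(as.numeric(counts), k = smoothK))
}

binCenters <- function(hist) {
  (hist@binEdges[-1L] + hist@binEdges[-length(hist@binEdges)]) / 2
}

#' Detect lean and fat peaks and derive the segmentation threshold
#'
#' The ROI histogram of an abdominal slice typically shows two peak
#' regions -- non-fat tissue at low SI and fat at high SI -- separated by a
#' local minimum.  This function locates the two highest-prominence local
#' maxima of the smoothed histogram, the minimum of the smoothed counts
#' strictly between them (plateau minima resolve to the plateau midpoint),
#' and sets the default threshold halfway between the local minimum and
#' the fat peak.
#'
#' @param hist a [SliceHistogram-class].
#' @return A [ThresholdModel-class] without a manual override.
#' @section Errors: A histogram without two local maxima after smoothing,
#'   or with fewer than two bins between the selected peaks, signals a
#'   \code{"noBimodalStructure"} condition; the caller must then supply a
#'   manual threshold.
#' @export
detectPeaks <- function(hist) {
  y <- hist@smoothedCounts
  centers <- binCenters(hist)
  peaks <- localMaxima(y)
  if (nrow(peaks) < 2L)
    stop(vatCondition("noBimodalStructure",
                      "histogram has no bimodal structure (fewer than 2 local maxima)"))
  peaks$prom <- peakProminence(peaks, y)
  peaks$pos <- (peaks$start + peaks$end) / 2
  ord <- order(-peaks$prom, -peaks$height, peaks$start)
  sel <- peaks[ord[1:2], ]
  sel <- sel[order(sel$pos), ]    # lean first, fat second
  gapBins <- sel$start[2] - sel$end[1] - 1L
  if (gapBins < 2L)
    stop(vatCondition("noBimodalStructure",
                      "fewer than 2 bins between the two histogram peaks"))
  between <- (sel$end[1] + 1L):(sel$start[2] - 1L)
  minVal <- min(y[between])
  atMin <- between[y[between] == minVal]
  localMinSI <- mean(range(centers[atMin]))   # plateau midpoint
  leanSI <- mean(range(centers[sel$start[1]:sel$end[1]]))
  fatSI <- mean(range(centers[sel$start[2]:sel$end[2]]))
  new("ThresholdModel",
      leanPeakSI = leanSI,
      localMinSI = localMinSI,
      fatPeakSI = fatSI,
      thresholdSI = (localMinSI + fatSI) / 2,
      manualOverride = NA_real_)
}

#' Segment the VAT pixels of one slice
#'
#' Classifies as VAT every ROI pixel whose signal intensity is greater
#' than or equal to the model's effective threshold (the manual override
#' when set, the halfway-rule default otherwise).
#'
#' @param slice 2-D numeric matrix of signal intensities.
#' @param roiSlice logical matrix: the abdominal ROI of this slice.
#' @param model a [ThresholdModel-class].
#' @return Logical matrix: the VAT mask (always a subset of the ROI).
#' @export
segmentSlice <- function(slice, roiSlice, model) {
  stopifnot(identical(dim(slice), dim(roiSlice)))
  thr <- effectiveThreshold(model)
  if (!is.finite(thr)) stop("threshold model has no finite threshold")
  roiSlice & (slice >= thr)
}

#' Segment a full image stack
#'
#' Runs per-slice histogram analysis ([sliceHistogram()], [detectPeaks()])
#' and thresholding ([segmentSlice()]) over a stack.  Thresholds are
#' per-slice.  Slices with an empty ROI yield an empty mask slice and a
#' \code{NULL} model.  Manual overrides replace the default threshold on
#' the named slices; a slice whose histogram lacks bimodal structure is an
#' error unless an override covers it.
#'
#' @param stack an [ImageStack-class].
#' @param roi logical 3-D array matching the stack: the abdominal ROI.
#' @param overrides named numeric vector of manual thresholds; names are
#'   slice indices (e.g. \code{c("7" = 0.6)}).
#' @param nBins,smoothK histogram parameters passed to [sliceHistogram()].
#' @return A list with elements \code{mask} (logical 3-D array),
#'   \code{models} (per-slice list of [ThresholdModel-class] or
#'   \code{NULL}), and \code{log} (data frame recording every empty slice,
#'   override and non-bimodal slice).
#' @export
segmentStack <- function(stack, roi, overrides = numeric(0),
                         nBins = 256L, smoothK = 5L) {
  stopifnot(identical(dim(roi), dim(stack@slices)))
  nz <- nSlices(stack)
  if (length(overrides)) {
    ok <- suppressWarnings(as.integer(names(overrides)))
    if (anyNA(ok) || any(ok < 1L | ok > nz))
      stop("override names must be valid slice indices")
  }
  mask <- array(FALSE, dim = dim(roi))
  models <- vector("list", nz)
  logRows <- list()
  for (k in seq_len(nz)) {
    sl <- stack@slices[, , k]
    rs <- roi[, , k]
    ov <- overrides[as.character(k)]
    hasOv <- length(ov) == 1L && !is.na(ov)
    if (!any(rs)) {
      logRows[[length(logRows) + 1L]] <-
        data.frame(slice = k, event = "empty-slice", threshold = NA_real_)
      next
    }
    h <- sliceHistogram(sl, rs, nBins = nBins, smoothK = smoothK)
    model <- tryCatch(detectPeaks(h), noBimodalStructure = function(e) e)
    if (inherits(model, "condition")) {
      if (!hasOv)
        stop(vatCondition("noBimodalStructure", sprintf(
          "slice %d: %s and no manual override supplied", k,
          conditionMessage(model))))
      model <- new("ThresholdModel",
                   leanPeakSI = NA_real_, localMinSI = NA_real_,
                   fatPeakSI = NA_real_, thresholdSI = NA_real_,
                   manualOverride = as.numeric(ov))
      logRows[[length(logRows) + 1L]] <-
        data.frame(slice = k, event = "no-bimodal-structure",
                   threshold = as.numeric(ov))
    }
    if (hasOv) {
      model@manualOverride <- as.numeric(ov)
      logRows[[length(logRows) + 1L]] <-
        data.frame(slice = k, event = "manual-override",
                   threshold = as.numeric(ov))
    }
    models[[k]] <- model
    mask[, , k] <- segmentSlice(sl, rs, model)
  }
  log <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(slice = integer(0), event = character(0),
               threshold = numeric(0))
  list(mask = mask, models = models, log = log)
}
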