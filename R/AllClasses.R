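#' @import methods
NULL

#' Axial MR image stack
#'
#' An ordered stack of axial slices of signal intensity (SI), stored as a
#' 3-D array \code{[x, y, slice]} with slice 1 the most caudal and slice
#' indices increasing cranially.  In-plane pixel spacing is isotropic.
#'
#' @slot slices 3-D numeric array of signal intensities.
#' @slot pixelSpacing in-plane pixel spacing in mm/pixel (isotropic).
#' @slot sliceThickness nominal slice thickness in mm.
#' @slot intersliceGap gap between adjacent slices in mm.
#'
#' @seealso [imageStack()], [effectiveSliceThickness()], [segmentStack()]
#' @exportClass ImageStack
setClass("ImageStack",
  representation(
    slices         = "array",
    pixelSpacing   = "numeric",
    sliceThickness = "numeric",
    intersliceGap  = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@slices)) != 3L)
    msg <- c(msg, "'slices' must be a 3-D array [x, y, slice]")
  if (length(object@pixelSpacing) != 1L || object@pixelSpacing <= 0)
    msg <- c(msg, "'pixelSpacing' must be a single positive value (mm)")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "'sliceThickness' must be a single positive value (mm)")
  if (length(object@intersliceGap) != 1L || object@intersliceGap < 0)
    msg <- c(msg, "'intersliceGap' must be a single non-negative value (mm)")
  if (length(msg)) msg else TRUE
})

#' Per-slice signal-intensity histogram
#'
#' Histogram of the signal intensities of the pixels inside the abdominal
#' ROI of one slice, together with a smoothed version used for peak
#' detection.  Bins are left-closed with the last bin closed on both sides.
#'
#' @slot binEdges numeric vector of length \code{nBins + 1}.
#' @slot counts integer bin counts; they sum to the ROI pixel count.
#' @slot smoothedCounts moving-average smoothed counts (same length).
#'
#' @seealso [sliceHistogram()], [detectPeaks()]
#' @exportClass SliceHistogram
setClass("SliceHistogram",
  representation(
    binEdges       = "numeric",
    counts         = "integer",
    smoothedCounts = "numeric"
  )
)

setValidity("SliceHistogram", function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@counts) + 1L)
    msg <- c(msg, "'binEdges' must have one more element than 'counts'")
  if (length(object@smoothedCounts) != length(object@counts))
    msg <- c(msg, "'smoothedCounts' must match 'counts' in length")
  if (any(object@counts < 0L))
    msg <- c(msg, "'counts' must be non-negative")
  if (is.unsorted(object@binEdges, strictly = FALSE))
    msg <- c(msg, "'binEdges' must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Slice threshold model
#'
#' Location of the lean (non-fat) peak, the local minimum and the fat peak
#' of a slice's smoothed SI histogram, and the segmentation threshold.  The
#' default threshold lies halfway between the local minimum and the fat
#' peak; \code{manualOverride} (when not \code{NA}) replaces it.
#'
#' @slot leanPeakSI SI of the lean-tissue peak.
#' @slot localMinSI SI of the local minimum between the peaks.
#' @slot fatPeakSI SI of the fat peak.
#' @slot thresholdSI default threshold, \code{(localMinSI + fatPeakSI)/2}.
#' @slot manualOverride optional manual threshold (\code{NA} if unset).
#'
#' @seealso [detectPeaks()], [segmentSlice()], [effectiveThreshold()]
#' @exportClass ThresholdModel
setClass("ThresholdModel",
  representation(
    leanPeakSI     = "numeric",
    localMinSI     = "numeric",
    fatPeakSI      = "numeric",
    thresholdSI    = "numeric",
    manualOverride = "numeric"
  ),
  prototype(manualOverride = NA_real_)
)

setValidity("ThresholdModel", function(object) {
  msg <- character()
  peaks <- c(object@leanPeakSI, object@localMinSI, object@fatPeakSI)
  if (all(is.finite(peaks))) {
    if (!(object@leanPeakSI < object@localMinSI &&
          object@localMinSI < object@fatPeakSI))
      msg <- c(msg, "must satisfy leanPeakSI < localMinSI < fatPeakSI")
    if (is.finite(object@thresholdSI) &&
        (object@thresholdSI < object@localMinSI - 1e-9 ||
         object@thresholdSI > object@fatPeakSI + 1e-9))
      msg <- c(msg, "'thresholdSI' must lie in [localMinSI, fatPeakSI]")
  } else if (is.na(object@manualOverride)) {
    msg <- c(msg, "peak locations may be NA only when manualOverride is set")
  }
  if (length(msg)) msg else TRUE
})

#' Per-slice VAT area series
#'
#' VAT areas per slice (cm^2) on the stack's axial grid together with the
#' effective slice thickness ST (cm), the axial pitch used in volumetry.
#'
#' @slot areasCm2 numeric vector, one VAT area per slice, in cm^2.
#' @slot stCm effective slice thickness in cm (nominal thickness + gap).
#'
#' @seealso [sliceAreas()], [totalVatVolume()], [areaAtLandmark()]
#' @exportClass AreaSeries
setClass("AreaSeries",
  representation(areasCm2 = "numeric", stCm = "numeric")
)

setValidity("AreaSeries", function(object) {
  msg <- character()
  if (any(object@areasCm2 < 0, na.rm = TRUE))
    msg <- c(msg, "'areasCm2' must be non-negative")
  if (length(object@stCm) != 1L || !is.finite(object@stCm) || object@stCm <= 0)
    msg <- c(msg, "'stCm' must be a single positive value (cm)")
  if (length(msg)) msg else TRUE
})

#' Synthetic abdominal phantom
#'
#' A simulated axial image stack with a known abdominal ROI, an exact
#' ground-truth VAT mask and its exact volume, plus a landmark table.  Used
#' to validate segmentation and volumetry end to end.
#'
#' @slot image an [ImageStack-class].
#' @slot roi logical 3-D array: the visceral (abdominal-cavity) ROI.
#' @slot truthMask logical 3-D array: ground-truth VAT pixels (subset of roi).
#' @slot truthVolumeMl exact VAT volume in ml implied by \code{truthMask}.
#' @slot landmarks named integer vector of landmark slice indices.
#' @slot separabilityWarning \code{TRUE} when the lean/fat intensity
#'   distributions overlap too much for reliable histogram separation.
#' @slot spec the [phantomSpec()] list the phantom was generated from.
#'
#' @seealso [generatePhantom()], [segmentStack()]
#' @exportClass VATPhantom
setClass("VATPhantom",
  representation(
    image               = "ImageStack",
    roi                 = "array",
    truthMask           = "array",
    truthVolumeMl       = "numeric",
    landmarks           = "integer",
    separabilityWarning = "logical",
    spec                = "list"
  )
)

setValidity("VATPhantom", function(object) {
  msg <- character()
  dimg <- dim(object@image@slices)
  if (!identical(dim(object@roi), dimg))
    msg <- c(msg, "'roi' must have the same dimensions as the image")
  if (!identical(dim(object@truthMask), dimg))
    msg <- c(msg, "'truthMask' must have the same dimensions as the image")
  if (any(object@truthMask & !object@roi))
    msg <- c(msg, "'truthMask' must be a subset of 'roi'")
  if (length(msg)) msg else TRUE
})

#' Through-origin scaling fit
#'
#' The scaling factor f for one landmark, gender stratum and slice count:
#' the slope of the least-squares regression, constrained through the
#' origin, of partial slice volume (area x ST) on total VAT volume.  f is
#' the fraction of total VAT volume captured by the landmark window.
#'
#' @slot landmark landmark name (e.g. \code{"L3L4"}).
#' @slot gender \code{"F"}, \code{"M"}, or \code{"all"} for pooled fits.
#' @slot nSlices 1 or 5.
#' @slot f fitted scaling factor (unitless fraction).
#' @slot rSquared uncentered R^2 of the partial-volume-on-total fit.
#' @slot rSquaredVolumeOnArea uncentered R^2 of the opposite orientation.
#' @slot nSubjects number of subjects in the fit.
#'
#' @seealso [fitScalingFactor()], [predictVolume()]
#' @exportClass ScalingFit
setClass("ScalingFit",
  representation(
    landmark             = "character",
    gender               = "character",
    nSlices              = "integer",
    f                    = "numeric",
    rSquared             = "numeric",
    rSquaredVolumeOnArea = "numeric",
    nSubjects            = "integer"
  )
)

setValidity("ScalingFit", function(object) {
  msg <- character()
  if (!object@nSlices %in% c(1L, 5L))
    msg <- c(msg, "'nSlices' must be 1 or 5")
  if (is.finite(object@f) && object@f < 0)
    msg <- c(msg, "'f' must be non-negative for non-negative inputs")
  if (is.finite(object@rSquared) && object@rSquared > 1 + 1e-12)
    msg <- c(msg, "'rSquared' cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' Bland-Altman agreement statistics
#'
#' Bias (mean of predicted - measured) and the standard deviation sigma of
#' the differences, the agreement measure used to rank landmarks.  Limits
#' of agreement (bias +/- 1.96 sigma) are carried for plotting.
#'
#' @slot bias mean difference, predicted - measured, in ml.
#' @slot sigma sample SD (n - 1 denominator) of the differences, in ml.
#' @slot n number of pairs.
#' @slot loaLower,loaUpper 95\% limits of agreement in ml.
#'
#' @seealso [blandAltman()], [plotBlandAltman()]
#' @exportClass AgreementStats
setClass("AgreementStats",
  representation(
    bias     = "numeric",
    sigma    = "numeric",
    n        = "integer",
    loaLower = "numeric",
    loaUpper = "numeric"
  )
)

setValidity("AgreementStats", function(object) {
  msg <- character()
  if (is.finite(object@sigma) && object@sigma < 0)
    msg <- c(msg, "'sigma' must be non-negative")
  if (object@n < 2L)
    msg <- c(msg, "'n' must be at least 2")
  if (length(msg)) msg else TRUE
})
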