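#' Accessors for vatmri classes
#'
#' Small accessor generics: slot access stays behind functions so internal
#' representations can change without breaking user code.
#'
#' @param x a vatmri object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))

#' @rdname accessors
#' @export
setGeneric("intersliceGap", function(x) standardGeneric("intersliceGap"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("thresholdSI", function(x) standardGeneric("thresholdSI"))

#' @rdname accessors
#' @export
setGeneric("effectiveThreshold", function(x) standardGeneric("effectiveThreshold"))

#' @rdname accessors
#' @export
setGeneric("scalingFactor", function(x) standardGeneric("scalingFactor"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("biasMl", function(x) standardGeneric("biasMl"))

#' @rdname accessors
#' @export
setGeneric("sigmaMl", function(x) standardGeneric("sigmaMl"))

#' @rdname accessors
#' @export
setGeneric("truthVolume", function(x) standardGeneric("truthVolume"))

#' @rdname accessors
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))

#' @rdname accessors
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' @rdname accessors
#' @export
setGeneric("areas", function(x) standardGeneric("areas"))

#' @rdname accessors
#' @export
setGeneric("stCm", function(x) standardGeneric("stCm"))

## ---- ImageStack ----

#' @rdname accessors
#' @export
setMethod("pixelSpacing", "ImageStack", function(x) x@pixelSpacing)

#' @rdname accessors
#' @export
setMethod("sliceThickness", "ImageStack", function(x) x@sliceThickness)

#' @rdname accessors
#' @export
setMethod("intersliceGap", "ImageStack", function(x) x@intersliceGap)

#' @rdname accessors
#' @export
setMethod("nSlices", "ImageStack", function(x) dim(x@slices)[3L])

#' @rdname accessors
#' @export
setMethod("imageData", "ImageStack", function(x) x@slices)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@slices)
  cat(sprintf(
    "ImageStack: %d x %d pixels, %d slices (caudal -> cranial)\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel spacing %.3f mm, slice thickness %g mm, gap %g mm\n",
              object@pixelSpacing, object@sliceThickness, object@intersliceGap))
  cat(sprintf("  effective slice thickness %.3f cm, axial extent %.2f cm\n",
              effectiveSliceThickness(object@sliceThickness, object@intersliceGap),
              axialExtent(object)))
})

## ---- SliceHistogram ----

#' @rdname accessors
#' @export
setMethod("nSlices", "VATPhantom", function(x) nSlices(x@image))

setMethod("show", "SliceHistogram", function(object) {
  cat(sprintf("SliceHistogram: %d bins on [%.4g, %.4g], %d ROI pixels\n",
              length(object@counts), min(object@binEdges),
              max(object@binEdges), sum(object@counts)))
})

## ---- ThresholdModel ----

#' @rdname accessors
#' @export
setMethod("thresholdSI", "ThresholdModel", function(x) x@thresholdSI)

#' @rdname accessors
#' @export
setMethod("effectiveThreshold", "ThresholdModel", function(x) {
  if (!is.na(x@manualOverride)) x@manualOverride else x@thresholdSI
})

setMethod("show", "ThresholdModel", function(object) {
  cat("ThresholdModel\n")
  cat(sprintf("  lean peak %.4g | local min %.4g | fat peak %.4g\n",
              object@leanPeakSI, object@localMinSI, object@fatPeakSI))
  cat(sprintf("  default threshold %.4g%s\n", object@thresholdSI,
              if (!is.na(object@manualOverride))
                sprintf(" (manual override %.4g)", object@manualOverride)
              else ""))
})

## ---- AreaSeries ----

#' @rdname accessors
#' @export
setMethod("areas", "AreaSeries", function(x) x@areasCm2)

#' @rdname accessors
#' @export
setMethod("stCm", "AreaSeries", function(x) x@stCm)

#' @rdname accessors
#' @export
setMethod("nSlices", "AreaSeries", function(x) length(x@areasCm2))

setMethod("show", "AreaSeries", function(object) {
  cat(sprintf("AreaSeries: %d slices, ST %.3f cm, total %.1f cm^2\n",
              length(object@areasCm2), object@stCm, sum(object@areasCm2)))
})

## ---- VATPhantom ----

#' @rdname accessors
#' @export
setMethod("imageData", "VATPhantom", function(x) x@image@slices)

#' @rdname accessors
#' @export
setMethod("truthVolume", "VATPhantom", function(x) x@truthVolumeMl)

#' @rdname accessors
#' @export
setMethod("truthMask", "VATPhantom", function(x) x@truthMask)

#' @rdname accessors
#' @export
setMethod("roiMask", "VATPhantom", function(x) x@roi)

#' @rdname accessors
#' @export
setMethod("landmarks", "VATPhantom", function(x) x@landmarks)

setMethod("show", "VATPhantom", function(object) {
  cat("VATPhantom\n")
  show(object@image)
  cat(sprintf("  ground-truth VAT volume %.1f ml (%d VAT pixels)\n",
              object@truthVolumeMl, sum(object@truthMask)))
  if (object@separabilityWarning)
    cat("  WARNING: lean/fat intensity distributions barely separable\n")
})

## ---- ScalingFit ----

#' @rdname accessors
#' @export
setMethod("scalingFactor", "ScalingFit", function(x) x@f)

#' @rdname accessors
#' @export
setMethod("rSquared", "ScalingFit", function(x) x@rSquared)

setMethod("show", "ScalingFit", function(object) {
  cat(sprintf("ScalingFit: %s / %s / %d slice(s)\n",
              object@landmark, object@gender, object@nSlices))
  cat(sprintf("  f = %.5f, R^2 = %.4f (n = %d)\n",
              object@f, object@rSquared, object@nSubjects))
})

## ---- AgreementStats ----

#' @rdname accessors
#' @export
setMethod("biasMl", "AgreementStats", function(x) x@bias)

#' @rdname accessors
#' @export
setMethod("sigmaMl", "AgreementStats", function(x) x@sigma)

setMethod("show", "AgreementStats", function(object) {
  cat(sprintf("AgreementStats: bias %.1f ml, sigma %.1f ml (n = %d)\n",
              object@bias, object@sigma, object@n))
  cat(sprintf("  95%% limits of agreement [%.1f, %.1f] ml\n",
              object@loaLower, object@loaUpper))
})
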