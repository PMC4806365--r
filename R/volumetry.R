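#' Effective slice thickness
#'
#' Nominal slice thickness plus interslice gap, converted to cm.  This is
#' the axial pitch of the slice grid: multiplying a slice's area by it
#' gives that slice's volume contribution, implicitly interpolating the
#' unobserved tissue in the gap.
#'
#' @param thicknessMm nominal slice thickness in mm (> 0).
#' @param gapMm interslice gap in mm (>= 0).
#' @return Effective slice thickness ST in cm.
#' @examples
#' effectiveSliceThickness(10, 0.5)  # 1.05 cm
#' @export
effectiveSliceThickness <- function(thicknessMm, gapMm = 0) {
  if (!is.finite(thicknessMm) || thicknessMm <= 0)
    stop("'thicknessMm' must be positive")
  if (!is.finite(gapMm) || gapMm < 0)
    stop("'gapMm' must be non-negative")
  (thicknessMm + gapMm) / 10
}

#' Validate a landmark table
#'
#' A landmark table maps the anatomical reference levels -- the pelvic
#' floor (PF), femoral heads (FH), intervertebral spaces L5-S1 .. L1-L2,
#' the umbilicus (UM) and the diaphragm (D) -- to slice indices (1-based,
#' caudal to cranial).  PF must be the most caudal and D the most cranial
#' of the named levels, with the lumbar spaces in anatomical order.
#'
#' @param landmarks named integer vector; names from
#'   \code{c("PF","FH","L5S1","UM","L4L5","L3L4","L2L3","L1L2","D")}.
#' @param nTotal optional stack size; indices must fall in \code{[1, nTotal]}.
#' @return The validated landmark table (invisibly), as a named integer
#'   vector.
#' @export
validateLandmarks <- function(landmarks, nTotal = NULL) {
  landmarks <- structure(as.integer(landmarks), names = names(landmarks))
  unknown <- setdiff(names(landmarks), LANDMARK_ORDER)
  if (length(unknown))
    stop("unknown landmark name(s): ", paste(unknown, collapse = ", "))
  if (!is.null(nTotal) &&
      any(landmarks < 1L | landmarks > nTotal))
    stop("landmark indices must lie within the stack (1..", nTotal, ")")
  lum <- intersect(c("L5S1", "L4L5", "L3L4", "L2L3", "L1L2"), names(landmarks))
  if (length(lum) > 1L && is.unsorted(landmarks[lum]))
    stop("lumbar landmarks must be in caudal-to-cranial index order")
  if ("PF" %in% names(landmarks) &&
      any(landmarks["PF"] > landmarks[setdiff(names(landmarks), "PF")]))
    stop("PF must be the most caudal landmark")
  if ("D" %in% names(landmarks) &&
      any(landmarks["D"] < landmarks[setdiff(names(landmarks), "D")]))
    stop("D must be the most cranial landmark")
  invisible(landmarks)
}

#' Per-slice VAT areas from a mask
#'
#' Converts per-slice VAT pixel counts into areas: pixel count times pixel
#' area, reported in cm^2.
#'
#' @param mask logical 3-D array of VAT-classified pixels.
#' @param pixelSpacingMm isotropic in-plane pixel spacing in mm (> 0).
#' @param stCm effective slice thickness in cm (see
#'   [effectiveSliceThickness()]).
#' @return An [AreaSeries-class].
#' @examples
#' m <- array(FALSE, c(10, 10, 2)); m[1:10, 1:10, 1] <- TRUE
#' areas(sliceAreas(m, pixelSpacingMm = 530 / 480, stCm = 1.05))
#' @export
sliceAreas <- function(mask, pixelSpacingMm, stCm) {
  if (!is.finite(pixelSpacingMm) || pixelSpacingMm <= 0)
    stop("'pixelSpacingMm' must be positive")
  counts <- apply(mask, 3L, sum)
  new("AreaSeries",
      areasCm2 = counts * pixelSpacingMm^2 / 100,
      stCm = stCm)
}

#' Construct an AreaSeries from areas
#'
#' @param areasCm2 numeric vector of per-slice VAT areas in cm^2.
#' @param stCm effective slice thickness in cm.
#' @return An [AreaSeries-class].
#' @export
areaSeries <- function(areasCm2, stCm) {
  new("AreaSeries", areasCm2 = as.numeric(areasCm2), stCm = as.numeric(stCm))
}

#' Total VAT volume between pelvic floor and diaphragm
#'
#' Sums per-slice VAT areas over the slice range from PF to D (inclusive)
#' and multiplies by the effective slice thickness.  Slices outside the
#' PF-D range do not contribute.
#'
#' @param series an [AreaSeries-class].
#' @param landmarks named integer vector with at least \code{PF} and
#'   \code{D}.
#' @return Total VAT volume V_VAT-T in ml (cm^3).
#' @export
totalVatVolume <- function(series, landmarks) {
  if (!all(c("PF", "D") %in% names(landmarks)))
    stop("'landmarks' must define PF and D")
  pf <- as.integer(landmarks[["PF"]])
  d <- as.integer(landmarks[["D"]])
  if (pf > d) stop("PF index exceeds D index")
  n <- length(series@areasCm2)
  if (pf < 1L || d > n)
    stop("PF-D range exceeds the area series (1..", n, ")")
  sum(series@areasCm2[pf:d]) * series@stCm
}

#' Axial height relative to the L3-L4 reference
#'
#' Height (cm) of a slice relative to the L3-L4 intervertebral space,
#' positive for more cranial slices: \code{(index - index_L3L4) * ST}.
#' With the study geometry (10 mm slices, 0.5 mm gap, ST = 1.05 cm) the
#' slices one, three and seven positions cranial to L3-L4 sit at 1.05,
#' 3.15 and 7.35 cm.
#'
#' @param index slice index (may be a vector).
#' @param landmarks named integer vector containing \code{L3L4}.
#' @param stCm effective slice thickness in cm.
#' @return h_ref in cm.
#' @export
hRef <- function(index, landmarks, stCm) {
  if (!"L3L4" %in% names(landmarks))
    stop("'landmarks' must define L3L4")
  (index - as.integer(landmarks[["L3L4"]])) * stCm
}

#' Slice window at a landmark
#'
#' Returns the slice indices entering the single- or five-slice VAT area
#' at a landmark.  Five-slice windows are symmetric about the landmark
#' slice, except at the femoral heads where all slices lie at or above the
#' landmark: the default window is the landmark slice plus the four
#' immediately cranial slices (\code{fhMode = "include"}); the strict
#' reading, the five slices starting one above the landmark, is available
#' as \code{fhMode = "above"}.
#'
#' @param landmark landmark name.
#' @param nSlices window size, 1 or 5.
#' @param landmarks named integer landmark table.
#' @param nTotal number of slices in the stack (bounds check).
#' @param fhMode femoral-head window convention, \code{"include"} (default)
#'   or \code{"above"}.
#' @return Integer vector of slice indices.
#' @examples
#' lm <- c(L3L4 = 20, FH = 5, PF = 1, D = 40)
#' landmarkWindow("L3L4", 5, lm, 40)  # 18:22
#' landmarkWindow("FH", 5, lm, 40)    # 5:9
#' @export
landmarkWindow <- function(landmark, nSlices, landmarks, nTotal,
                           fhMode = c("include", "above")) {
  fhMode <- match.arg(fhMode)
  if (!nSlices %in% c(1L, 5L)) stop("'nSlices' must be 1 or 5")
  if (!landmark %in% names(landmarks))
    stop("landmark '", landmark, "' not in the landmark table")
  L <- as.integer(landmarks[[landmark]])
  window <- if (nSlices == 1L) {
    L
  } else if (landmark == "FH") {
    if (fhMode == "include") L:(L + 4L) else (L + 1L):(L + 5L)
  } else {
    (L - 2L):(L + 2L)
  }
  if (any(window < 1L) || any(window > nTotal))
    stop("five-slice window at '", landmark, "' exceeds the stack (1..",
         nTotal, ")")
  window
}

#' VAT area at a landmark window
#'
#' Single-slice windows return that slice's area (A_VAT-1); five-slice
#' windows return the sum of the five areas (A_VAT-5), so that the
#' five-slice scaling factor is roughly five times the single-slice one.
#'
#' @param series an [AreaSeries-class].
#' @param window integer vector of slice indices (from [landmarkWindow()]).
#' @return Area in cm^2.
#' @export
areaAtLandmark <- function(series, window) {
  n <- length(series@areasCm2)
  if (any(window < 1L) || any(window > n))
    stop("window indices exceed the area series (1..", n, ")")
  sum(series@areasCm2[window])
}
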