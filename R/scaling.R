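#' Fit a through-origin scaling factor
#'
#' For one landmark, slice count and (optionally) gender stratum, regresses
#' the partial slice volume \code{p_i = A_i x ST} on the measured total VAT
#' volume \code{v_i} with the line constrained through the origin.  The
#' slope \code{f = sum(p v) / sum(v^2)} is the scaling factor: the fraction
#' of total VAT volume captured by the landmark window.  The uncentered
#' through-origin R^2 of the fit is stored, along with the R^2 of the
#' opposite orientation (total regressed on partial) since through-origin
#' R^2 is not symmetric in the axes.
#'
#' @param cohort data frame of subject records with columns \code{gender},
#'   \code{v_vat_t_ml} and per-landmark area columns \code{a1_<landmark>} /
#'   \code{a5_<landmark>} in cm^2 (see [generateCohort()] /
#'   [readCohortCsv()]).
#' @param landmark landmark name, e.g. \code{"L3L4"}.
#' @param nSlices 1 or 5.
#' @param stCm effective slice thickness in cm.
#' @param gender \code{"F"} or \code{"M"} to restrict the fit to one
#'   stratum; \code{NULL} pools both genders.
#' @return A [ScalingFit-class].
#' @examples
#' coh <- data.frame(gender = "F", v_vat_t_ml = c(4000, 5000, 6000),
#'                   a1_L3L4 = 0.045 * c(4000, 5000, 6000) / 1.05)
#' scalingFactor(fitScalingFactor(coh, "L3L4", 1, stCm = 1.05))  # 0.045
#' @export
fitScalingFactor <- function(cohort, landmark, nSlices, stCm, gender = NULL) {
  nSlices <- as.integer(nSlices)
  if (!nSlices %in% c(1L, 5L)) stop("'nSlices' must be 1 or 5")
  if (!is.null(gender)) cohort <- cohort[cohort$gender == gender, , drop = FALSE]
  col <- sprintf("a%d_%s", nSlices, landmark)
  if (!col %in% names(cohort))
    stop("cohort has no column '", col, "'")
  keep <- is.finite(cohort[[col]]) & is.finite(cohort$v_vat_t_ml)
  A <- cohort[[col]][keep]
  v <- cohort$v_vat_t_ml[keep]
  if (length(v) < 2L && length(v) != 1L)
    stop("need at least 2 subjects (or exactly 1 for a one-point fit)")
  if (all(v == 0)) stop("all total volumes are zero; slope undefined")
  p <- A * stCm
  f <- sum(p * v) / sum(v^2)
  r2 <- if (sum(p^2) > 0) rSquaredThroughOrigin(p, v, f) else NA_real_
  # opposite orientation: v = g * p
  r2alt <- if (sum(p^2) > 0 && sum(v^2) > 0) {
    g <- sum(p * v) / sum(p^2)
    rSquaredThroughOrigin(v, p, g)
  } else NA_real_
  new("ScalingFit",
      landmark = landmark,
      gender = if (is.null(gender)) "all" else gender,
      nSlices = nSlices,
      f = f,
      rSquared = r2,
      rSquaredVolumeOnArea = r2alt,
      nSubjects = length(v))
}

#' Predict total VAT volume from a partial area
#'
#' Inverts the scaling relation: \code{V = A x ST / f}, where A is the
#' single- or five-slice VAT area (cm^2), ST the effective slice thickness
#' (cm) and f the scaling factor fitted for that landmark, gender and
#' slice count.
#'
#' @param areaCm2 measured VAT area in cm^2 (vectorised).
#' @param stCm effective slice thickness in cm.
#' @param f scaling factor (> 0); a [ScalingFit-class] is also accepted.
#' @return Predicted total VAT volume in ml.
#' @examples
#' predictVolume(210, 1.05, 0.045)  # 4900 ml
#' @export
predictVolume <- function(areaCm2, stCm, f) {
  if (is(f, "ScalingFit")) f <- f@f
  if (!is.finite(f) || f <= 0) stop("'f' must be positive")
  areaCm2 * stCm / f
}

#' Uncentered R-squared of a through-origin fit
#'
#' For a line through the origin the conventional centered R^2 is not
#' appropriate; the uncentered form compares residuals with the raw sum of
#' squares of the response:
#' \code{R^2 = 1 - sum((p - f v)^2) / sum(p^2)}.
#'
#' @param p response values (here partial volumes).
#' @param v predictor values (here total volumes).
#' @param f slope of the through-origin line.
#' @return Uncentered R^2 (at most 1; can be negative for a bad slope).
#' @export
rSquaredThroughOrigin <- function(p, v, f) {
  if (length(p) != length(v)) stop("'p' and 'v' must have equal length")
  ssTot <- sum(p^2)
  if (ssTot == 0) stop("sum of squares of 'p' is zero; R^2 undefined")
  1 - sum((p - f * v)^2) / ssTot
}
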