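#' Specification of a synthetic cohort
#'
#' Parameters of a table-level simulated study population: stratum sizes,
#' per-gender axial VAT-area templates, between-subject variability,
#' per-slice area measurement noise, demographic ranges and the slice-grid
#' geometry.  The defaults emulate the morbidly obese study population:
#' 94 females / 36 males, ages 18.6-70.7 years, BMI above 40 kg/m^2, a
#' 40-slice grid at 1.05 cm pitch, female areas peaking just cranial to
#' L3-L4 and male areas several cm higher.
#'
#' @param nFemale,nMale stratum sizes.
#' @param femaleProfile,maleProfile [axialProfile()] templates.
#' @param betweenSubjectCv fractional between-subject variability applied
#'   to amplitude and width (mean-preserving lognormal jitter); the peak
#'   offset is jittered additively with SD \code{cv * widthCm}, since a
#'   fractional CV is degenerate for an offset near zero.
#' @param areaNoiseSdCm2 SD of the additive per-slice area measurement
#'   noise, in cm^2 (negative draws truncate at 0 and are counted).
#' @param ageRange,bmiRange uniform sampling ranges (years, kg/m^2).
#' @param nSlicesGrid number of slices between pelvic floor and diaphragm.
#' @param sliceThicknessMm,intersliceGapMm slice geometry in mm.
#' @param landmarks named integer landmark table on the grid.
#' @param fhMode femoral-head five-slice window convention (see
#'   [landmarkWindow()]).
#' @param seed integer RNG seed (required).
#' @return A validated \code{CohortSpec} list.
#' @export
cohortSpec <- function(nFemale = 94L, nMale = 36L,
                       femaleProfile = femaleVatProfile(),
                       maleProfile = maleVatProfile(),
                       betweenSubjectCv = 0.25,
                       areaNoiseSdCm2 = 8,
                       ageRange = c(18.6, 70.7),
                       bmiRange = c(40.1, 64.1),
                       nSlicesGrid = 40L,
                       sliceThicknessMm = 10,
                       intersliceGapMm = 0.5,
                       landmarks = defaultLandmarks(nSlicesGrid),
                       fhMode = c("include", "above"),
                       seed) {
  if (missing(seed)) stop("'seed' is required")
  fhMode <- match.arg(fhMode)
  if (nFemale < 0 || nMale < 0) stop("stratum sizes must be non-negative")
  if (betweenSubjectCv < 0) stop("'betweenSubjectCv' must be non-negative")
  if (areaNoiseSdCm2 < 0) stop("'areaNoiseSdCm2' must be non-negative")
  if (diff(ageRange) <= 0 || diff(bmiRange) <= 0)
    stop("age/BMI ranges must be non-degenerate")
  stopifnot(inherits(femaleProfile, "AxialProfile"),
            inherits(maleProfile, "AxialProfile"))
  landmarks <- validateLandmarks(landmarks, nSlicesGrid)
  structure(
    list(nFemale = as.integer(nFemale), nMale = as.integer(nMale),
         femaleProfile = femaleProfile, maleProfile = maleProfile,
         betweenSubjectCv = betweenSubjectCv,
         areaNoiseSdCm2 = areaNoiseSdCm2,
         ageRange = ageRange, bmiRange = bmiRange,
         nSlicesGrid = as.integer(nSlicesGrid),
         sliceThicknessMm = sliceThicknessMm,
         intersliceGapMm = intersliceGapMm,
         landmarks = landmarks, fhMode = fhMode,
         seed = as.integer(seed)),
    class = "CohortSpec")
}

#' Generate a synthetic cohort of subject records
#'
#' Simulates one subject record per patient: a true axial area profile
#' (the gender template jittered by the between-subject CV), the true
#' total VAT volume (sum of the true per-slice areas between PF and D
#' times ST), and noisy observed areas from which the single-slice
#' (A_VAT-1) and five-slice (A_VAT-5, summed over the window) landmark
#' areas are read off.  Ages and BMIs are sampled uniformly within the
#' spec ranges.  Generation is fully determined by \code{spec$seed}.
#'
#' @param spec a [cohortSpec()].
#' @return A data frame with one row per subject and columns \code{id},
#'   \code{gender}, \code{age}, \code{bmi}, \code{v_vat_t_ml}, and
#'   \code{a1_<landmark>} / \code{a5_<landmark>} for each reference
#'   landmark.  Attributes: \code{stCm} (effective slice thickness),
#'   \code{landmarks}, and \code{truncatedAreas} (number of negative
#'   area draws truncated at zero).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  st <- effectiveSliceThickness(spec$sliceThicknessMm, spec$intersliceGapMm)
  lmTab <- spec$landmarks
  nGrid <- spec$nSlicesGrid
  h <- (seq_len(nGrid) - lmTab[["L3L4"]]) * st
  refLms <- intersect(REFERENCE_LANDMARKS, names(lmTab))
  windows1 <- lapply(refLms, landmarkWindow, nSlices = 1L,
                     landmarks = lmTab, nTotal = nGrid, fhMode = spec$fhMode)
  windows5 <- lapply(refLms, landmarkWindow, nSlices = 5L,
                     landmarks = lmTab, nTotal = nGrid, fhMode = spec$fhMode)
  names(windows1) <- names(windows5) <- refLms

  genders <- c(rep("F", spec$nFemale), rep("M", spec$nMale))
  nTot <- length(genders)
  cv <- spec$betweenSubjectCv
  # variance decomposition of the between-subject CV: overall amount
  # (amplitude) carries the full CV, the axial position of the fat bulk
  # is jittered additively by cv x template width, and the distribution
  # width itself varies least (0.3 cv) -- subjects differ mainly in how
  # much fat they carry and where its bulk sits, less in its spread
  sdlogA <- sqrt(log(1 + cv^2))
  sdlogW <- sqrt(log(1 + (0.3 * cv)^2))
  truncated <- 0L

  rows <- withSeed(spec$seed, lapply(seq_len(nTot), function(i) {
    tpl <- if (genders[i] == "F") spec$femaleProfile else spec$maleProfile
    amp <- tpl$amplitudeCm2 *
      if (cv > 0) stats::rlnorm(1, -sdlogA^2 / 2, sdlogA) else 1
    wid <- tpl$widthCm *
      if (cv > 0) stats::rlnorm(1, -sdlogW^2 / 2, sdlogW) else 1
    off <- tpl$peakOffsetCm +
      if (cv > 0) stats::rnorm(1, 0, cv * tpl$widthCm) else 0
    trueAreas <- amp * snShape(h, off, wid, tpl$skewness)
    v <- sum(trueAreas[lmTab[["PF"]]:lmTab[["D"]]]) * st
    obs <- trueAreas +
      if (spec$areaNoiseSdCm2 > 0)
        stats::rnorm(nGrid, 0, spec$areaNoiseSdCm2) else 0
    neg <- obs < 0
    truncated <<- truncated + sum(neg)
    obs[neg] <- 0
    rec <- list(
      id = sprintf("S%03d", i),
      gender = genders[i],
      age = stats::runif(1, spec$ageRange[1], spec$ageRange[2]),
      bmi = stats::runif(1, spec$bmiRange[1], spec$bmiRange[2]),
      v_vat_t_ml = v)
    for (lm in refLms) {
      rec[[sprintf("a1_%s", lm)]] <- obs[windows1[[lm]]]
      rec[[sprintf("a5_%s", lm)]] <- sum(obs[windows5[[lm]]])
    }
    as.data.frame(rec, stringsAsFactors = FALSE)
  }))
  cohort <- do.call(rbind, rows)
  attr(cohort, "stCm") <- st
  attr(cohort, "landmarks") <- lmTab
  attr(cohort, "truncatedAreas") <- truncated
  cohort
}

#' Generate a cohort with a known constant landmark fraction
#'
#' Simulates subjects whose single-slice landmark area is exactly
#' \code{A = f_true x V / ST} plus Gaussian measurement noise (and the
#' five-slice area \code{5 f_true x V / ST} plus noise), with total
#' volumes drawn from a truncated normal.  Because the generating fraction
#' is known, the through-origin fit must recover \code{f_true} and the
#' Bland-Altman sigma of the predictions has the analytic expectation
#' \code{noiseSd x ST / f_true}; used to validate the scaling and
#' agreement machinery at scale.
#'
#' @param n number of subjects.
#' @param fTrue generating single-slice fraction.
#' @param noiseSdCm2 SD of the additive area noise in cm^2.
#' @param stCm effective slice thickness in cm.
#' @param volMeanMl,volSdMl mean and SD of the total-volume distribution
#'   (ml), truncated below at 500 ml.
#' @param landmark landmark name used for the area columns.
#' @param gender gender label for all subjects.
#' @param seed integer RNG seed (required).
#' @return A cohort data frame in the schema of [generateCohort()],
#'   restricted to one landmark, with attribute \code{stCm}.
#' @export
generateProportionalCohort <- function(n, fTrue, noiseSdCm2 = 0,
                                       stCm = 1.05, volMeanMl = 4900,
                                       volSdMl = 1700, landmark = "L3L4",
                                       gender = "F", seed) {
  if (missing(seed)) stop("'seed' is required")
  if (!is.finite(fTrue) || fTrue <= 0) stop("'fTrue' must be positive")
  withSeed(seed, {
    v <- pmax(stats::rnorm(n, volMeanMl, volSdMl), 500)
    a1 <- fTrue * v / stCm +
      if (noiseSdCm2 > 0) stats::rnorm(n, 0, noiseSdCm2) else 0
    a5 <- 5 * fTrue * v / stCm +
      if (noiseSdCm2 > 0) stats::rnorm(n, 0, noiseSdCm2) else 0
    age <- stats::runif(n, 18.6, 70.7)
    bmi <- stats::runif(n, 40.1, 64.1)
    cohort <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      gender = gender, age = age, bmi = bmi,
      v_vat_t_ml = v, stringsAsFactors = FALSE)
    cohort[[sprintf("a1_%s", landmark)]] <- pmax(a1, 0)
    cohort[[sprintf("a5_%s", landmark)]] <- pmax(a5, 0)
    attr(cohort, "stCm") <- stCm
    cohort
  })
}
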