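test_that("degenerate-noise phantoms contain exactly the two peak values", {
  spec <- phantomSpec(nSlices = 21, matrixSize = 64, pixelSpacingMm = 6.6,
                      leanPeakSd = 0, fatPeakSd = 0, noiseSd = 0, seed = 1)
  ph <- generatePhantom(spec)
  roiVals <- imageData(ph)[roiMask(ph)]
  expect_setequal(unique(roiVals), c(0.2, 0.8))
})

test_that("stack geometry arithmetic matches the acquisition parameters", {
  spec <- phantomSpec(nSlices = 50, matrixSize = 32, satRingWidthMm = 10,
                      pixelSpacingMm = 6, seed = 2)
  ph <- generatePhantom(spec)
  expect_equal(axialExtent(ph@image), 52.5)   # 50 x 1.05 cm
  expect_equal(effectiveSliceThickness(sliceThickness(ph@image),
                                       intersliceGap(ph@image)), 1.05)
})

test_that("phantom generation is deterministic in the seed", {
  s1 <- generatePhantom(phantomSpec(nSlices = 21, matrixSize = 48, pixelSpacingMm = 8.8, seed = 3))
  s2 <- generatePhantom(phantomSpec(nSlices = 21, matrixSize = 48, pixelSpacingMm = 8.8, seed = 3))
  expect_identical(imageData(s1), imageData(s2))
  expect_identical(truthMask(s1), truthMask(s2))
  s3 <- generatePhantom(phantomSpec(nSlices = 21, matrixSize = 48, pixelSpacingMm = 8.8, seed = 4))
  expect_false(identical(imageData(s1), imageData(s3)))
})

test_that("phantom ground truth is internally consistent", {
  ph <- generatePhantom(phantomSpec(nSlices = 25, matrixSize = 64, pixelSpacingMm = 6.6, seed = 5))
  sp <- pixelSpacing(ph@image)
  st <- effectiveSliceThickness(sliceThickness(ph@image),
                                intersliceGap(ph@image))
  expect_identical(truthVolume(ph), sum(truthMask(ph)) * sp^2 / 100 * st)
  expect_false(any(truthMask(ph) & !roiMask(ph)))
  # the landmark table respects the caudal-cranial ordering
  expect_silent(validateLandmarks(landmarks(ph), nSlices(ph)))
})

test_that("overlapping intensity peaks raise the separability flag", {
  phBad <- generatePhantom(phantomSpec(nSlices = 21, matrixSize = 48, pixelSpacingMm = 8.8,
                                       leanPeakMean = 0.45, fatPeakMean = 0.55,
                                       leanPeakSd = 0.05, fatPeakSd = 0.05,
                                       seed = 6))
  expect_true(phBad@separabilityWarning)
  phGood <- generatePhantom(phantomSpec(nSlices = 21, matrixSize = 48, pixelSpacingMm = 8.8, seed = 6))
  expect_false(phGood@separabilityWarning)
})

test_that("profiles with no VAT in the stack are rejected", {
  far <- axialProfile(peakOffsetCm = 500, widthCm = 3, amplitudeCm2 = 100)
  expect_error(generatePhantom(phantomSpec(nSlices = 21, matrixSize = 48, pixelSpacingMm = 8.8,
                                           vatProfile = far, seed = 7)),
               "zero VAT area")
})

test_that("default cohorts have the study's strata and demographics", {
  coh <- generateCohort(cohortSpec(seed = 8))
  expect_identical(nrow(coh), 130L)
  expect_identical(sum(coh$gender == "F"), 94L)
  expect_identical(sum(coh$gender == "M"), 36L)
  expect_true(all(coh$bmi > 40))
  expect_true(all(coh$v_vat_t_ml > 0))
  # five-slice areas dominate single-slice areas per landmark
  for (lm in c("L3L4", "UM", "FH"))
    expect_true(all(coh[[paste0("a5_", lm)]] >=
                      coh[[paste0("a1_", lm)]] - 1e-9))
})

test_that("cohort generation is seed-deterministic", {
  c1 <- generateCohort(cohortSpec(seed = 9))
  c2 <- generateCohort(cohortSpec(seed = 9))
  expect_identical(c1, c2)
  c3 <- generateCohort(cohortSpec(seed = 10))
  expect_false(identical(c1$v_vat_t_ml, c3$v_vat_t_ml))
})

test_that("the noiseless limit collapses to identical subjects and R^2 = 1", {
  spec <- cohortSpec(nFemale = 10, nMale = 5, betweenSubjectCv = 0,
                     areaNoiseSdCm2 = 0, seed = 11)
  coh <- generateCohort(spec)
  f <- coh[coh$gender == "F", ]
  expect_equal(length(unique(f$v_vat_t_ml)), 1L)
  expect_equal(length(unique(f$a1_L3L4)), 1L)
  for (ns in c(1, 5)) {
    fit <- fitScalingFactor(coh, "L3L4", ns, attr(coh, "stCm"), gender = "F")
    expect_equal(rSquared(fit), 1)
  }
})

test_that("negative area draws are truncated and counted", {
  spec <- cohortSpec(nFemale = 20, nMale = 0, areaNoiseSdCm2 = 400, seed = 12)
  coh <- generateCohort(spec)
  expect_gt(attr(coh, "truncatedAreas"), 0)
  areaCols <- grep("^a[15]_", names(coh), value = TRUE)
  expect_true(all(as.matrix(coh[areaCols]) >= 0))
})

test_that("gender templates put the median-area maximum where the study does", {
  st <- 1.05
  h <- (1:40 - 16) * st
  fArea <- evalProfile(femaleVatProfile(), h)
  mArea <- evalProfile(maleVatProfile(), h)
  hF <- h[which.max(fArea)]
  hM <- h[which.max(mArea)]
  expect_true(hF >= -1.05 && hF <= 2.10)
  expect_true(hM >= 3.15 && hM <= 7.35)
  # a male template shifted cranially keeps its maximum above L3-L4
  shifted <- axialProfile(4.2, 14.18, 305, 1)
  expect_gt(h[which.max(evalProfile(shifted, h))], 0)
})

test_that("proportional cohorts embed the generating fraction exactly", {
  coh <- generateProportionalCohort(50, fTrue = 0.045, noiseSdCm2 = 0,
                                    seed = 13)
  fit <- fitScalingFactor(coh, "L3L4", 1, attr(coh, "stCm"))
  expect_equal(scalingFactor(fit), 0.045)
  expect_equal(rSquared(fit), 1)
  fit5 <- fitScalingFactor(coh, "L3L4", 5, attr(coh, "stCm"))
  expect_equal(scalingFactor(fit5), 5 * 0.045)
})
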