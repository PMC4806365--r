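test_that("effective slice thickness is thickness plus gap, in cm", {
  expect_equal(effectiveSliceThickness(10, 0.5), 1.05)
  expect_equal(effectiveSliceThickness(10, 0), 1.0)
  expect_equal(effectiveSliceThickness(5, 0.5), 0.55)
  expect_error(effectiveSliceThickness(0, 0.5))
  expect_error(effectiveSliceThickness(10, -1))
})

test_that("slice areas are pixel count times pixel area", {
  m <- array(FALSE, c(20, 20, 2))
  m[1:10, 1:10, 1] <- TRUE  # 100 pixels
  sp <- 530 / 480           # the study's reconstruction spacing
  ser <- sliceAreas(m, sp, 1.05)
  expect_equal(areas(ser)[1], 100 * sp^2 / 100)
  expect_equal(round(areas(ser)[1], 3), 1.219)
  expect_equal(areas(ser)[2], 0)
  # doubling the spacing quadruples the area
  expect_equal(areas(sliceAreas(m, 2 * sp, 1.05))[1], 4 * areas(ser)[1])
})

test_that("total volume sums PF-D areas times ST", {
  ser <- areaSeries(rep(100, 40), 1.05)
  lm <- c(PF = 1, D = 40)
  expect_equal(totalVatVolume(ser, lm), 40 * 100 * 1.05)  # 4200 ml
  expect_equal(totalVatVolume(areaSeries(rep(0, 40), 1.05), lm), 0)
  # slices outside [PF, D] are excluded
  ser2 <- areaSeries(c(999, rep(100, 38), 999), 1.05)
  expect_equal(totalVatVolume(ser2, c(PF = 2, D = 39)), 38 * 100 * 1.05)
  expect_error(totalVatVolume(ser, c(PF = 10, D = 5)))
})

test_that("volume is additive over partitions of the PF-D range", {
  set.seed(21)
  ser <- areaSeries(runif(40, 0, 300), 1.05)
  whole <- totalVatVolume(ser, c(PF = 1, D = 40))
  parts <- totalVatVolume(ser, c(PF = 1, D = 17)) +
    totalVatVolume(ser, c(PF = 18, D = 29)) +
    totalVatVolume(ser, c(PF = 30, D = 40))
  expect_equal(whole, parts)
})

test_that("h_ref is affine in slice index with slope ST and zero at L3-L4", {
  lm <- c(L3L4 = 16L)
  st <- effectiveSliceThickness(10, 0.5)
  expect_equal(hRef(17, lm, st), 1.05)
  expect_equal(hRef(15, lm, st), -1.05)
  expect_equal(hRef(19, lm, st), 3.15)
  expect_equal(hRef(23, lm, st), 7.35)
  expect_equal(hRef(16, lm, st), 0)
  idx <- 1:40
  expect_equal(diff(hRef(idx, lm, st)), rep(st, 39))
})

test_that("landmark windows are symmetric except at the femoral heads", {
  lm <- c(PF = 1L, FH = 5L, L3L4 = 20L, UM = 14L, D = 40L)
  expect_identical(landmarkWindow("L3L4", 5, lm, 40), 18:22)
  expect_identical(landmarkWindow("UM", 1, lm, 40), 14L)
  fh <- landmarkWindow("FH", 5, lm, 40)
  expect_identical(fh, 5:9)
  expect_true(all(fh >= lm[["FH"]]))   # all at or above the landmark
  expect_identical(landmarkWindow("FH", 5, lm, 40, fhMode = "above"), 6:10)
  # windows exceeding the stack name the landmark
  expect_error(landmarkWindow("L3L4", 5, c(L3L4 = 2L), 40), "L3L4")
})

test_that("landmark areas sum over five-slice windows", {
  ser <- areaSeries(rep(200, 30), 1.05)
  lm <- c(L3L4 = 15L)
  w5 <- landmarkWindow("L3L4", 5, lm, 30)
  w1 <- landmarkWindow("L3L4", 1, lm, 30)
  expect_equal(areaAtLandmark(ser, w5), 1000)
  expect_equal(areaAtLandmark(ser, w1), 200)
  # uniform series: A5 = 5 * A1 exactly
  expect_equal(areaAtLandmark(ser, w5), 5 * areaAtLandmark(ser, w1))
  # non-negative areas: A5 >= A1 when the window contains the slice
  set.seed(31)
  ser2 <- areaSeries(runif(30, 0, 100), 1.05)
  expect_gte(areaAtLandmark(ser2, w5), areaAtLandmark(ser2, w1))
})

test_that("landmark tables are validated for order and bounds", {
  good <- c(PF = 1L, FH = 6L, L5S1 = 10L, L4L5 = 13L, UM = 14L,
            L3L4 = 16L, L2L3 = 19L, L1L2 = 22L, D = 40L)
  expect_silent(validateLandmarks(good, 40))
  bad <- good; bad[["L3L4"]] <- 9L   # lumbar order violated
  expect_error(validateLandmarks(bad, 40))
  expect_error(validateLandmarks(c(good, XX = 3L), 40))
  expect_error(validateLandmarks(good, 30))  # D out of bounds
})
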