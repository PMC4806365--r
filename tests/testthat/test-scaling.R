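test_that("exact proportionality recovers the generating slope with R^2 = 1", {
  v <- c(2000, 4000, 4900, 7000, 10200)
  coh <- data.frame(gender = "F", v_vat_t_ml = v,
                    a1_L3L4 = 0.045 * v / 1.05)
  fit <- fitScalingFactor(coh, "L3L4", 1, stCm = 1.05)
  expect_equal(scalingFactor(fit), 0.045)
  expect_equal(rSquared(fit), 1)
})

test_that("a single record gives the one-point slope p/v", {
  coh <- data.frame(gender = "M", v_vat_t_ml = 8000, a1_L1L2 = 300)
  fit <- fitScalingFactor(coh, "L1L2", 1, stCm = 1.05)
  expect_equal(scalingFactor(fit), 300 * 1.05 / 8000)
})

test_that("fitted slope matches a grid-search oracle on seeded noisy data", {
  for (s in 1:50) {
    set.seed(s)
    v <- runif(20, 2000, 12000)
    a <- 0.045 * v / 1.05 + rnorm(20, 0, 15)
    coh <- data.frame(gender = "F", v_vat_t_ml = v, a1_L3L4 = a)
    fit <- fitScalingFactor(coh, "L3L4", 1, stCm = 1.05)
    fOracle <- gridSearchSlope(a * 1.05, v, lower = 0.02, upper = 0.08)
    expect_equal(scalingFactor(fit), fOracle, tolerance = 1e-4)
    # the fitted slope maximizes the through-origin R^2 over the grid
    r2fit <- rSquaredThroughOrigin(a * 1.05, v, scalingFactor(fit))
    r2oracle <- rSquaredThroughOrigin(a * 1.05, v, fOracle)
    expect_gte(r2fit + 1e-10, r2oracle)
  }
})

test_that("orthogonal data give slope 0 and R^2 0", {
  p <- c(1, -1); v <- c(1, 1)
  f <- sum(p * v) / sum(v^2)
  expect_equal(f, 0)
  expect_equal(rSquaredThroughOrigin(p, v, f), 0)
})

test_that("scaling is equivariant under rescaling of areas and volumes", {
  set.seed(42)
  v <- runif(30, 2000, 12000)
  a <- 0.05 * v / 1.05 + rnorm(30, 0, 20)
  coh <- function(a, v) data.frame(gender = "F", v_vat_t_ml = v, a1_UM = a)
  f0 <- fitScalingFactor(coh(a, v), "UM", 1, 1.05)
  fA <- fitScalingFactor(coh(3 * a, v), "UM", 1, 1.05)
  fV <- fitScalingFactor(coh(a, 3 * v), "UM", 1, 1.05)
  expect_equal(scalingFactor(fA), 3 * scalingFactor(f0))
  expect_equal(scalingFactor(fV), scalingFactor(f0) / 3)
  expect_equal(rSquared(fA), rSquared(f0))
  expect_equal(rSquared(fV), rSquared(f0))
})

test_that("volume prediction is A x ST / f and inverts the scaling", {
  expect_equal(predictVolume(210, 1.05, 0.045), 4900)
  expect_equal(predictVolume(0, 1.05, 0.045), 0)
  # inversion identity: predicting from the implied area recovers V
  for (V in c(1400, 4900, 10200)) {
    A <- 0.045 * V / 1.05
    expect_equal(predictVolume(A, 1.05, 0.045), V)
  }
  expect_error(predictVolume(210, 1.05, 0))
  expect_error(predictVolume(210, 1.05, -0.1))
})

test_that("degenerate volume inputs are rejected", {
  coh <- data.frame(gender = "F", v_vat_t_ml = c(0, 0), a1_L3L4 = c(1, 2))
  expect_error(fitScalingFactor(coh, "L3L4", 1, 1.05))
  expect_error(rSquaredThroughOrigin(c(0, 0), c(1, 2), 0.5))
})
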