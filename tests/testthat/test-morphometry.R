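test_that("coefficient of variation follows its definition", {
  expect_equal(coefficientOfVariation(c(10, 10, 10)), 0)
  expect_equal(coefficientOfVariation(c(1, 2, 3)), 0.5)  # sample sd 1, mean 2
  set.seed(1)
  x <- runif(100, 1, 5)
  for (k in c(0.1, 3, 250))
    expect_equal(coefficientOfVariation(k * x), coefficientOfVariation(x))
  expect_error(coefficientOfVariation(c(5)), "at least 2")
  expect_error(coefficientOfVariation(c(-1, 1)), "mean")
})

test_that("line-ROI CV stays at the noise floor on uniform planes", {
  g <- makeChromatinPlane(0, readSd = 0, seed = 1)
  cv <- linearRoiCV(g$plane, g$contour, inwardLengthUm = 4)
  expect_lt(cv, 1e-12)
  expect_error(linearRoiCV(g$plane, g$contour, inwardLengthUm = 20),
               "exits the nucleus")
  # avoidance mask invalidates crossing ROIs
  avoid <- matrix(TRUE, nrow(g$plane), ncol(g$plane))
  expect_error(linearRoiCV(g$plane, g$contour, 4, avoidMask = avoid),
               "avoidance")
})

test_that("beta ratio separates uniform, explicit and rim-only planes", {
  img <- matrix(1, 256, 256)
  px <- 0.145
  ctr <- (256 - 1) / 2 * px
  ct <- ellipseContour(50 * px, 50 * px, center = c(ctr, ctr))
  expect_equal(betaRatio(img, ct), 1)
  # edge mean 200, interior mean 100
  masks <- nuclearRegionMasks(img, ct)
  img2 <- img * 100
  img2[masks$edge] <- 200
  expect_equal(betaRatio(img2, ct, masks = masks), 2)
  rim <- makeLaminPlanes(rimBoost = 0.5, seed = 1)
  expect_gt(betaRatio(rim$lamin, rim$contour), 1)
  # multiplicative gain invariance
  expect_equal(betaRatio(3.7 * img2, ct, masks = masks),
               betaRatio(img2, ct, masks = masks))
})

test_that("major-axis profiles are normalized and recover slopes", {
  lam <- makeLaminPlanes(breakpointFrac = 0.3, edgeSlope = -0.5,
                         interiorLevel = 0.8, seed = 1)
  prof <- majorAxisProfile(lam$lamin, lam$contour)
  expect_equal(max(prof@intensity), 1)
  expect_true(all(diff(prof@position) > 0))
  nich <- makeLaminPlanes(breakpointFrac = 0.21, edgeSlope = -0.765,
                          interiorLevel = 0.75, seed = 2)
  fit <- twoSegmentFit(majorAxisProfile(nich$lamin, nich$contour))
  expect_lt(abs(fit@edgeSlope + 0.765), 0.02)
  # uniform disk: flat profile, degenerate fit, slope ~ 0
  unif <- makeLaminPlanes(breakpointFrac = 0.5, edgeSlope = -1e-9,
                          interiorLevel = 1, seed = 1)
  ufit <- twoSegmentFit(majorAxisProfile(unif$lamin, unif$contour))
  expect_true(ufit@degenerate)
  expect_lt(abs(ufit@edgeSlope), 1e-6)
})

test_that("two-segment fit recovers exact breakpoints and is stable", {
  mkprof <- function(bp, slopeE = -0.7, level = 0.75, n = 101) {
    p <- seq(0, 1, length.out = n)
    vb <- 1 + slopeE * bp
    i <- ifelse(p < bp, 1 + slopeE * p, vb + (level - vb) * (p - bp) / (1 - bp))
    new("IntensityProfile", position = p, intensity = i / max(i))
  }
  f21 <- twoSegmentFit(mkprof(0.21))
  expect_equal(f21@occupancy, 21)
  expect_equal(f21@edgeSlope, -0.7, tolerance = 1e-9)
  f64 <- twoSegmentFit(mkprof(0.64, slopeE = -0.183, level = 0.88))
  expect_equal(f64@occupancy, 64)
  # resampling x2 moves the breakpoint by < 0.01
  f2 <- twoSegmentFit(mkprof(0.21, n = 201))
  expect_lt(abs(f2@breakpoint - f21@breakpoint), 0.01)
  expect_error(twoSegmentFit(mkprof(0.21, n = 8)), "at least 10")
})

test_that("two-segment breakpoint bias is below 0.02 at SNR 20", {
  n <- 101
  p <- seq(0, 1, length.out = n)
  bp <- 0.35; slopeE <- -0.7; level <- 0.75
  vb <- 1 + slopeE * bp
  clean <- ifelse(p < bp, 1 + slopeE * p,
                  vb + (level - vb) * (p - bp) / (1 - bp))
  est <- vapply(1:100, function(s) {
    set.seed(s)
    y <- clean + rnorm(n, sd = mean(clean) / 20)  # SNR 20
    twoSegmentFit(new("IntensityProfile", position = p,
                      intensity = y / max(y)))@breakpoint
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE) - bp), 0.02)
})

test_that("nuclear/cytoplasmic ratio follows region means", {
  plane <- matrix(1, 40, 40)
  nuc <- matrix(FALSE, 40, 40); nuc[5:15, 5:15] <- TRUE
  cyt <- matrix(FALSE, 40, 40); cyt[25:35, 25:35] <- TRUE
  expect_equal(nucCytoRatio(plane, nuc, cyt), 1)
  plane[nuc] <- 2
  expect_equal(nucCytoRatio(plane, nuc, cyt), 2)
  expect_equal(nucCytoRatio(5 * plane, nuc, cyt), 2)  # gain invariance
  expect_error(nucCytoRatio(plane, nuc, nuc), "disjoint")
  big <- matrix(FALSE, 40, 40); big[1:40, 1:20] <- TRUE; big[nuc] <- FALSE
  expect_warning(nucCytoRatio(plane, nuc, big), "2x")
})
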