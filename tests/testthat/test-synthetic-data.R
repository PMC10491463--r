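test_that("generators are byte-identical for a fixed seed", {
  expect_identical(makeNucleusStack(c(3, 2, 2), readSd = 0.05, seed = 4),
                   makeNucleusStack(c(3, 2, 2), readSd = 0.05, seed = 4))
  expect_identical(makeLaminPlanes(edgeCv = 0.2, readSd = 0.01, seed = 9),
                   makeLaminPlanes(edgeCv = 0.2, readSd = 0.01, seed = 9))
  expect_identical(makeChromatinPlane(1, seed = 3), makeChromatinPlane(1, seed = 3))
  expect_identical(makeFiberImage(10, 15, 30, seed = 5),
                   makeFiberImage(10, 15, 30, seed = 5))
  expect_identical(makeCorrelationPair(0.3, 0.5, seed = 2),
                   makeCorrelationPair(0.3, 0.5, seed = 2))
  expect_identical(makeCreepCurve(noiseSd = 0.01, seed = 6),
                   makeCreepCurve(noiseSd = 0.01, seed = 6))
  ct <- ellipseContour(6, 4, center = c(8, 8))
  expect_identical(makeApproachEvents(ct, 100, 0.5, seed = 8),
                   makeApproachEvents(ct, 100, 0.5, seed = 8))
  expect_identical(
    makeTrackingMovie(ct, nMolecules = 20, nFrames = 20, seed = 8),
    makeTrackingMovie(ct, nMolecules = 20, nFrames = 20, seed = 8))
})

test_that("nucleus stack volume matches the sphere and rejects oversize", {
  st <- makeNucleusStack(c(5, 5, 5), voxelSize = c(0.2, 0.2, 0.2))
  vol <- sum(st$stack > 0.5) * 0.2^3
  expect_lt(abs(vol - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.02)
  expect_error(
    makeNucleusStack(c(9, 3, 3), fovUm = c(10, 10, 10)),
    "field of view")
})

test_that("lamin plane generator encodes exact two-segment profiles", {
  lam <- makeLaminPlanes(breakpointFrac = 0.21, edgeSlope = -0.765,
                         interiorLevel = 0.75, seed = 1)
  fit <- twoSegmentFit(majorAxisProfile(lam$lamin, lam$contour))
  expect_lt(abs(fit@breakpoint - 0.21), 0.01)
  expect_lt(abs(fit@edgeSlope + 0.765), 0.02)
  expect_error(makeLaminPlanes(breakpointFrac = 1.2), "breakpointFrac")
  # flat profile: degenerate two-segment fit with near-zero slope
  fl <- makeLaminPlanes(breakpointFrac = 0.5, edgeSlope = -1e-9,
                        interiorLevel = 1, seed = 1)
  ffit <- twoSegmentFit(majorAxisProfile(fl$lamin, fl$contour))
  expect_true(ffit@degenerate)
  expect_lt(abs(ffit@edgeSlope), 1e-6)
  # edgeCv = 0 leaves the edge band at the additive-noise floor
  nz <- makeLaminPlanes(edgeCv = 0, readSd = 0, seed = 1)
  masks <- nuclearRegionMasks(nz$lamin, nz$contour)
  expect_lt(coefficientOfVariation(nz$phospho[masks$edge]), 1e-12)
})

test_that("chromatin clustering drives the line-ROI CV monotonically", {
  cvAt <- function(strength, seeds) vapply(seeds, function(s) {
    g <- makeChromatinPlane(strength, seed = s)
    linearRoiCV(g$plane, g$contour, inwardLengthUm = 4.5,
                startAngle = s)
  }, numeric(1))
  seeds <- 1:25
  low <- cvAt(0.4, seeds); high <- cvAt(1.5, seeds)
  expect_gt(mean(high), mean(low))
  # zero clustering sits at the noise floor
  flat <- makeChromatinPlane(0, readSd = 0.01, seed = 2)
  cv0 <- linearRoiCV(flat$plane, flat$contour, 4.5)
  expect_lt(cv0, 0.05)
})

test_that("fiber images encode the requested orientation statistics", {
  fi <- makeFiberImage(30, 0, 60, seed = 3, readSd = 0)
  expect_equal(directionalityHistogram(fi$plane)@peakAngle, 30)
  empty <- makeFiberImage(0, 15, 0, seed = 1, readSd = 0.01)
  h <- directionalityHistogram(empty$plane)
  expect_lt(max(h@weight) / min(h@weight), 3)  # background only, near-flat
})

test_that("correlation pair fractions and creep closed forms hold", {
  cp <- makeCorrelationPair(0.4, 0.6, seed = 6)
  # equal-area default: band and interior areas within a few percent
  expect_lt(abs(sum(cp$edgeMask) / sum(cp$interiorMask) - 1), 0.05)
  cc <- makeCreepCurve(E = 0.23, eta = 0.12, forcePN = 140, areaA2 = 78.54,
                       noiseSd = 0, nSamples = 200)
  expect_equal(cc@strain[1], 0)
  long <- makeCreepCurve(E = 0.23, eta = 0.12, duration = 40, nSamples = 500)
  expect_lt(abs(long@strain[500] - stressFromForce(140, 78.54) / 0.23), 1e-6)
  # printed-parameter plateau: sigma0/E = 0.775
  expect_lt(abs(stressFromForce(140, 78.54) / 0.23 - 0.775), 5e-4)
})

test_that("approach-event generator honours the translocation probability", {
  ct <- ellipseContour(8, 5, n = 256, center = c(10, 10))
  ae1 <- makeApproachEvents(ct, nEvents = 400, pCross = 1, seed = 1)
  expect_true(all(ae1$events$crossed))
  ae0 <- makeApproachEvents(ct, nEvents = 400, pCross = 0, seed = 1)
  expect_false(any(ae0$events$crossed))
  dec <- makeApproachEvents(
    ct, nEvents = 3000,
    pCross = function(r) pmin(pmax(0.7 - 0.05 * r, 0), 1), seed = 3)
  ev <- classifyCrossings(dec$tracks, dec$profile)
  sl <- fitCrossingSlope(crossingRatioVsRadius(ev), nPerm = 0)
  expect_lt(sl$alpha, 0)
  expect_lt(sl$pValue, 0.005)
})
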