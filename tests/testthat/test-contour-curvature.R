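test_that("contour construction normalizes orientation and validates", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  cw <- nuclearContour(10 * cos(-th), 10 * sin(-th))  # clockwise input
  expect_gt(nucleomech:::.polygonArea(cw@x, cw@y), 0)
  expect_error(nuclearContour(c(0, 1, 2), c(0, 1, 0)), "at least 8")
  # bowtie-like path with a transversal mid-edge crossing is rejected
  vx <- c(0, 2.5, 5, 5, 2.5, 0); vy <- c(0, 2.5, 5, 0, 1.5, 3)
  sub <- function(v) as.vector(rbind(v, v + c(diff(v), v[1] - v[6]) / 2))
  expect_error(nuclearContour(sub(vx), sub(vy)), "self-intersecting")
})

test_that("contour extraction recovers disks and ellipses, fails on blanks", {
  n <- 200; px <- 0.145
  X <- matrix(0:(n - 1), n, n) * px
  Y <- matrix(0:(n - 1), n, n, byrow = TRUE) * px
  ctr <- (n - 1) / 2 * px
  disk <- ifelse(sqrt((X - ctr)^2 + (Y - ctr)^2) <= 10, 1, 0)
  ct <- extractContour(disk, pixelSize = px)
  r <- sqrt((ct@x - ctr)^2 + (ct@y - ctr)^2)
  expect_lt(abs(mean(r) - 10), 0.5 * px)
  ell <- ifelse(((X - ctr) / 9)^2 + ((Y - ctr) / 3)^2 <= 1, 1, 0)
  ct2 <- extractContour(ell, pixelSize = px)
  ratio <- diff(range(ct2@x)) / diff(range(ct2@y))
  expect_lt(abs(ratio - 3) / 3, 0.02)
  expect_error(extractContour(matrix(0, 50, 50)), "no foreground")
  # a manual ROI always wins
  roi <- cbind(ctr + 4 * cos(seq(0, 2 * pi, length.out = 33)[-33]),
               ctr + 4 * sin(seq(0, 2 * pi, length.out = 33)[-33]))
  ct3 <- extractContour(disk, pixelSize = px, roi = roi)
  expect_equal(nrow(contourPoints(ct3)), 32L)
})

test_that("spline curvature matches analytic values on circle and ellipse", {
  pc <- splineCurvature(ellipseContour(10, 10, n = 256), nSamples = 200)
  expect_true(all(abs(curvature(pc)$kappa - 0.1) < 1e-3))
  pe <- splineCurvature(ellipseContour(2, 1, n = 512), nSamples = 800)
  expect_lt(abs(max(curvature(pe)$kappa) - 2) / 2, 0.01)   # a/b^2 at the tip
  expect_lt(abs(min(curvature(pe)$kappa) - 0.25) / 0.25, 0.01)  # b/a^2
})

test_that("radius of curvature is capped below the kappa floor", {
  prof <- splineCurvature(ellipseContour(400, 400, n = 720), nSamples = 100)
  expect_true(all(radiusOfCurvature(prof) <= 1 / prof@kappaFloor + 1e-9))
})

test_that("spline curvature is invariant to vertex rotation and density", {
  # equal-arc vertices so a cyclic rotation by 64 of 256 vertices shifts the
  # equal-arc sample grid onto itself
  pts <- equalArcVertices(function(t) 5 * cos(t) + 1.2 * cos(2 * t),
                          function(t) 4 * sin(t), n = 256)
  base <- splineCurvature(nuclearContour(pts[, 1], pts[, 2],
                                         checkSimple = FALSE),
                          nSamples = 128)
  idx <- c(65:256, 1:64)
  rot <- splineCurvature(nuclearContour(pts[idx, 1], pts[idx, 2],
                                        checkSimple = FALSE), nSamples = 128)
  k1 <- sort(base@kappa); k2 <- sort(rot@kappa)
  expect_lt(max(abs(k1 - k2)) / max(abs(k1)), 1e-6)
  dpts <- equalArcVertices(function(t) 5 * cos(t) + 1.2 * cos(2 * t),
                           function(t) 4 * sin(t), n = 512)
  dense <- splineCurvature(nuclearContour(dpts[, 1], dpts[, 2],
                                          checkSimple = FALSE),
                           nSamples = 128)
  expect_lt(max(abs(sort(dense@kappa) - k1)) / max(abs(k1)), 5e-3)
})

test_that("pooled curvature histogram recovers a Gaussian and flags circles", {
  set.seed(1)
  mkprof <- function(mu, sigma, n = 400) {
    k <- rnorm(n, mu, sigma)
    new("CurvatureProfile", s = seq_len(n) * 0.1, kappa = k,
        rEq = 1 / pmax(abs(k), 0.005), kappaFloor = 0.005,
        contour = ellipseContour(5, 5))
  }
  h <- curvatureHistogram(lapply(1:20, function(i) mkprof(0.06, 0.01)),
                          binWidth = 0.005)
  expect_false(h$fit@degenerate)
  expect_lt(abs(h$fit@mean - 0.06), 0.002)
  expect_lt(abs(h$fit@fwhm - 2.3548 * 0.01) / (2.3548 * 0.01), 0.05)
  # cohorts built with sigma ratio 1.7 show the amplitude ratio ~1.7
  h2 <- curvatureHistogram(lapply(1:20, function(i) mkprof(0.06, 0.017)),
                           binWidth = 0.005)
  expect_lt(abs(h$fit@amplitude / h2$fit@amplitude - 1.7), 0.1)
  # constant-curvature cohort (circles) is degenerate
  circ <- lapply(1:3, function(i) splineCurvature(ellipseContour(10, 10)))
  expect_error(curvatureHistogram(circ, binWidth = 0.025), "nonempty bins")
})

test_that("signed distance matches geometry and a dense-sampling oracle", {
  ct <- ellipseContour(10, 10, n = 256, center = c(0, 0))
  expect_lt(abs(signedDistance(ct, c(0, 0)) + 10), 0.01)
  onCt <- c(ct@x[5], ct@y[5])
  expect_lt(abs(signedDistance(ct, onCt)), 1e-9)
  # brute-force oracle: nearest vertex of a densely resampled polygon
  ct2 <- ellipseContour(8, 4, n = 128, center = c(1, 2))
  xc <- c(ct2@x, ct2@x[1]); yc <- c(ct2@y, ct2@y[1])
  tt <- seq(0, 1, length.out = 400)
  dx <- as.vector(outer(tt, diff(xc), "*") +
                  matrix(xc[-length(xc)], 400, 128, byrow = TRUE))
  dy <- as.vector(outer(tt, diff(yc), "*") +
                  matrix(yc[-length(yc)], 400, 128, byrow = TRUE))
  set.seed(7)
  pts <- cbind(runif(50, -9, 11), runif(50, -3, 7))
  d <- signedDistance(ct2, pts)
  oracle <- sqrt(apply((outer(pts[, 1], dx, "-"))^2 +
                       (outer(pts[, 2], dy, "-"))^2, 1, min))
  expect_lt(max(abs(abs(d) - oracle)), 1e-3)
})
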