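test_that("spot detection localizes isolated and paired spots", {
  tr <- data.frame(track_id = c(1, 2), frame = c(1, 1),
                   x_um = c(5.0, 8.0), y_um = c(6.0, 6.0))
  frames <- renderSpotFrames(tr, fovUm = c(14, 12), pixelSize = 0.145)
  set.seed(1)
  noisy <- frames[, , 1] + matrix(rnorm(length(frames[, , 1]), sd = 0.1),
                                  nrow(frames))
  det <- detectSpots(noisy)
  expect_equal(nrow(det), 2L)
  det <- det[order(det$x_um), ]
  expect_lt(max(abs(det$x_um - c(5, 8))), 0.5 * 0.145)
  expect_lt(max(abs(det$y_um - 6)), 0.5 * 0.145)
  expect_error(detectSpots(noisy, diameterUm = 0.2), "diameter")
})

test_that("detection rate is monotone nondecreasing in SNR", {
  rateAt <- function(snr, seeds) mean(vapply(seeds, function(s) {
    set.seed(s)
    tr <- data.frame(track_id = 1, frame = 1,
                     x_um = runif(1, 3, 6), y_um = runif(1, 3, 6))
    fr <- renderSpotFrames(tr, fovUm = c(9, 9), pixelSize = 0.145,
                           intensity = snr * 0.1)
    fr <- fr[, , 1] + matrix(rnorm(length(fr[, , 1]), sd = 0.1), nrow(fr))
    d <- detectSpots(fr)
    nrow(d) >= 1 && min(sqrt((d$x_um - tr$x_um)^2 +
                             (d$y_um - tr$y_um)^2)) < 0.3
  }, logical(1)))
  seeds <- 1:40
  rates <- vapply(c(2, 5, 10), rateAt, numeric(1), seeds = seeds)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})

test_that("greedy linking respects r_max and matches brute force", {
  # steady drift below r_max gives one full-length track
  sp <- lapply(1:5, function(f) data.frame(x_um = 0.3 * f, y_um = 1))
  tr <- linkTracks(sp)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 5L)
  # a 1.5 um jump breaks the track
  tr2 <- linkTracks(list(data.frame(x_um = 0, y_um = 0),
                         data.frame(x_um = 1.5, y_um = 0)))
  expect_equal(length(unique(tr2$track_id)), 2L)
  # hard r_max constraint on every emitted link
  set.seed(3)
  sp3 <- lapply(1:10, function(f)
    data.frame(x_um = runif(4, 0, 4), y_um = runif(4, 0, 4)))
  tr3 <- linkTracks(sp3)
  for (id in unique(tr3$track_id)) {
    g <- tr3[tr3$track_id == id, ]
    if (nrow(g) > 1)
      expect_true(all(sqrt(diff(g$x_um)^2 + diff(g$y_um)^2) <= 1 + 1e-12))
  }
  # two crossing trajectories: greedy equals optimal matching in >= 95%
  # of frame pairs over 200 seeds
  agree <- 0L; total <- 0L
  nf <- 41L
  for (s in 1:100) {
    set.seed(s)
    tA <- cbind(seq(0, 2, length.out = nf), seq(0, 2, length.out = nf)) +
      matrix(rnorm(2 * nf, sd = 0.03), nf, 2)
    tB <- cbind(seq(2, 0, length.out = nf), seq(0, 2, length.out = nf)) +
      matrix(rnorm(2 * nf, sd = 0.03), nf, 2)
    for (f in 1:(nf - 1)) {
      cur <- rbind(tA[f, ], tB[f, ]); nxt <- rbind(tA[f + 1, ], tB[f + 1, ])
      tr <- linkTracks(list(
        data.frame(x_um = cur[, 1], y_um = cur[, 2]),
        data.frame(x_um = nxt[, 1], y_um = nxt[, 2])))
      ids1 <- tr$track_id[tr$frame == 1]
      ids2 <- tr$track_id[tr$frame == 2]
      greedy <- match(ids1, ids2)  # next-frame index linked to each spot
      oracle <- bruteMatch2(cur, nxt)
      total <- total + 1L
      if (identical(is.na(greedy), is.na(oracle)) &&
          all(greedy == oracle, na.rm = TRUE)) agree <- agree + 1L
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("crossing classification matches generator ground truth", {
  ct <- ellipseContour(8, 5, n = 256, center = c(10, 10))
  ae <- makeApproachEvents(ct, nEvents = 2500, pCross = 0.5, seed = 7)
  ev <- classifyCrossings(ae$tracks, ae$profile)
  expect_equal(nrow(ev), nrow(ae$events))
  expect_lt(abs(mean(ev$crossed) - 0.5), 0.03)
  expect_error(classifyCrossings(ae$tracks, ct), "curvature profile")
  # two-point track straddling the envelope: one inward crossing
  prof <- splineCurvature(ellipseContour(10, 10, center = c(12, 12)))
  tr <- data.frame(track_id = 1L, frame = 1:2,
                   x_um = c(12 + 10.2, 12 + 9.8), y_um = c(12, 12))
  one <- classifyCrossings(tr, prof)
  expect_equal(nrow(one), 1L)
  expect_equal(one$direction, "in")
  expect_true(one$crossed)
  # track entirely outside the band: no events
  far <- data.frame(track_id = 1L, frame = 1:2,
                    x_um = c(12 + 14, 12 + 13), y_um = c(12, 12))
  expect_equal(nrow(classifyCrossings(far, prof)), 0L)
})

test_that("crossing classification is time-reversal symmetric", {
  ct <- ellipseContour(8, 5, n = 256, center = c(10, 10))
  mv <- makeTrackingMovie(ct, nMolecules = 50, nFrames = 60, pCross = 1,
                          seed = 4)
  fwd <- classifyCrossings(mv$tracks, mv$profile)
  rev <- mv$tracks
  rev$frame <- max(rev$frame) + 1L - rev$frame
  bwd <- classifyCrossings(rev, mv$profile)
  fIn <- fwd[fwd$crossed & fwd$direction == "in", ]
  bOut <- bwd[bwd$crossed & bwd$direction == "out", ]
  expect_equal(nrow(fIn), nrow(bOut))
  expect_equal(sort(fIn$track_id), sort(bOut$track_id))
})

test_that("binned crossing table and slope fit behave per closed forms", {
  ct <- ellipseContour(8, 5, n = 256, center = c(10, 10))
  all1 <- makeApproachEvents(ct, nEvents = 800, pCross = 1, seed = 2)
  ev1 <- classifyCrossings(all1$tracks, all1$profile)
  tab1 <- crossingRatioVsRadius(ev1, nBins = 5)
  expect_true(all(tab1$fraction == 1))
  half <- makeApproachEvents(ct, nEvents = 4000, pCross = 0.5, seed = 5)
  evh <- classifyCrossings(half$tracks, half$profile)
  tabh <- crossingRatioVsRadius(evh, nBins = 5)
  expect_true(all(abs(tabh$fraction - 0.5) <= 3 * tabh$se))
  # analytic linear generator matches per-bin within 2 SE
  pfun <- function(r) pmin(pmax(0.7 - 0.05 * r, 0), 1)
  lin <- makeApproachEvents(ct, nEvents = 6000, pCross = pfun, seed = 6)
  evl <- classifyCrossings(lin$tracks, lin$profile)
  tabl <- crossingRatioVsRadius(evl, nBins = 6)
  expTr <- vapply(seq_len(nrow(tabl)), function(b) {
    sel <- evl$rEq >= min(evl$rEq) # recompute per-bin expectation from rEq
    mean(pfun(evl$rEq[cut(evl$rEq,
      breaks = unique(quantile(evl$rEq, seq(0, 1, length.out = 7))),
      include.lowest = TRUE, labels = FALSE) == b]))
  }, numeric(1))
  expect_true(all(abs(tabl$fraction - expTr) <= 2 * tabl$se))
  # degenerate requests fail loudly
  expect_error(crossingRatioVsRadius(
    data.frame(rEq = rep(3, 10), crossed = TRUE), nBins = 4), "bin")
  expect_error(fitCrossingSlope(tab1[1:2, ]), "3 bins")
  expect_error(fitCrossingSlope(tab1), "zero-variance")
})

test_that("crossing-fraction estimator is unbiased at p = 0.3", {
  ct <- ellipseContour(8, 5, n = 256, center = c(10, 10))
  est <- vapply(1:50, function(s) {
    ae <- makeApproachEvents(ct, nEvents = 300, pCross = 0.3, seed = s)
    mean(classifyCrossings(ae$tracks, ae$profile)$crossed)
  }, numeric(1))
  # pooled binomial standard error over 50 x 300 approaches
  seP <- sqrt(0.3 * 0.7 / (50 * 300))
  expect_lt(abs(mean(est) - 0.3), 2 * seP)
})
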