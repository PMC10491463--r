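#' Single-molecule spot detection in one frame
#'
#' Laplacian-of-Gaussian detection: the frame is smoothed with a Gaussian
#' of sigma = diameter / (2 sqrt(2)) (in pixels), a Laplacian filter
#' highlights rapid intensity changes, and local maxima of the blob
#' response above a robust threshold (k times the MAD of the response) are
#' kept. Positions are refined to sub-pixel precision by an intensity
#' centroid over a diameter-wide window.
#'
#' @param frame numeric matrix \code{[x, y]}.
#' @param diameterUm estimated particle diameter in um (default 1.0).
#' @param pixelSize pixel size in um (default 0.145).
#' @param k quality threshold in MADs of the blob response (default 6).
#' @return data.frame with x_um, y_um, intensity, quality (one row per
#'   detected maximum).
#' @export
detectSpots <- function(frame, diameterUm = 1.0, pixelSize = 0.145, k = 6) {
  diamPx <- diameterUm / pixelSize
  if (diamPx < 2) stop("particle diameter below 2 pixels")
  sigma <- diamPx / (2 * sqrt(2))
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(frame),
                                          sigma = sigma))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- -EBImage::imageData(EBImage::filter2(EBImage::Image(sm), lap))
  thr <- k * mad(resp)
  nx <- nrow(resp); ny <- ncol(resp)
  core <- resp[2:(nx - 1), 2:(ny - 1)]
  isMax <- core > thr &
    core >= resp[1:(nx - 2), 2:(ny - 1)] & core >= resp[3:nx, 2:(ny - 1)] &
    core >= resp[2:(nx - 1), 1:(ny - 2)] & core >= resp[2:(nx - 1), 3:ny] &
    core >= resp[1:(nx - 2), 1:(ny - 2)] & core >= resp[3:nx, 3:ny] &
    core >= resp[1:(nx - 2), 3:ny] & core >= resp[3:nx, 1:(ny - 2)]
  idx <- which(isMax, arr.ind = TRUE) + 1L
  if (!nrow(idx))
    return(data.frame(x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), quality = numeric()))
  half <- as.integer(ceiling(diamPx / 2))
  out <- matrix(NA_real_, nrow(idx), 4)
  for (i in seq_len(nrow(idx))) {
    xi <- max(1, idx[i, 1] - half):min(nx, idx[i, 1] + half)
    yi <- max(1, idx[i, 2] - half):min(ny, idx[i, 2] + half)
    w <- pmax(sm[xi, yi, drop = FALSE], 0)
    sw <- sum(w)
    out[i, 1] <- if (sw > 0) sum(w * (xi - 1)) / sw else idx[i, 1] - 1
    out[i, 2] <- if (sw > 0)
      sum(t(w) * (yi - 1)) / sw else idx[i, 2] - 1
    out[i, 3] <- frame[idx[i, 1], idx[i, 2]]
    out[i, 4] <- resp[idx[i, 1], idx[i, 2]]
  }
  data.frame(x_um = out[, 1] * pixelSize, y_um = out[, 2] * pixelSize,
             intensity = out[, 3], quality = out[, 4])
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking: candidate pairs between
#' consecutive frames are taken in ascending distance order, each spot used
#' at most once, and no link longer than \code{rMaxUm} is made. Unmatched
#' spots start new tracks; there is no gap closing.
#'
#' @param spots either a list of per-frame data.frames (x_um, y_um) or one
#'   data.frame with a \code{frame} column.
#' @param rMaxUm maximum displacement per time step in um (default 1).
#' @param frameIntervalS frame interval metadata carried into the output.
#' @return data.frame with track_id, frame, x_um, y_um.
#' @export
linkTracks <- function(spots, rMaxUm = 1.0, frameIntervalS = 0.010) {
  if (is.data.frame(spots)) {
    stopifnot("frame" %in% names(spots))
    frames <- sort(unique(spots$frame))
    spots <- lapply(frames, function(f)
      spots[spots$frame == f, c("x_um", "y_um"), drop = FALSE])
  } else {
    frames <- seq_along(spots)
  }
  if (length(spots) < 2L) stop("need at least 2 frames to link")
  nextId <- 0L
  newIds <- function(n) {
    ids <- nextId + seq_len(n)
    nextId <<- nextId + n
    ids
  }
  cur <- spots[[1]]
  curIds <- newIds(nrow(cur))
  rows <- list(data.frame(track_id = curIds, frame = frames[1],
                          x_um = cur$x_um, y_um = cur$y_um))
  for (f in 2:length(spots)) {
    nxt <- spots[[f]]
    ids <- rep(NA_integer_, nrow(nxt))
    if (nrow(cur) && nrow(nxt)) {
      d <- sqrt(outer(cur$x_um, nxt$x_um, "-")^2 +
                outer(cur$y_um, nxt$y_um, "-")^2)
      cand <- which(d <= rMaxUm, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        usedCur <- logical(nrow(cur)); usedNxt <- logical(nrow(nxt))
        for (i in seq_len(nrow(cand))) {
          a <- cand[i, 1]; b <- cand[i, 2]
          if (!usedCur[a] && !usedNxt[b]) {
            ids[b] <- curIds[a]
            usedCur[a] <- TRUE; usedNxt[b] <- TRUE
          }
        }
      }
    }
    ids[is.na(ids)] <- newIds(sum(is.na(ids)))
    if (nrow(nxt))
      rows[[f]] <- data.frame(track_id = ids, frame = frames[f],
                              x_um = nxt$x_um, y_um = nxt$y_um)
    cur <- nxt; curIds <- ids
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  attr(out, "frameIntervalS") <- frameIntervalS
  out
}

#' Classify nuclear-envelope crossing events along tracks
#'
#' Scans consecutive position pairs of each track for envelope events
#' within the analysis band (default 5 pixels) around the contour. A step
#' whose start lies outside the nucleus inside the band is an inward
#' approach: a crossing when the signed distance changes sign
#' (cytosol to nucleus), a rejection when the molecule is found stopped at
#' the envelope (distance within \code{touchTol}). Steps from just inside
#' the envelope to outside are outward crossings. Each event carries the
#' curvature radius rEq of the nearest contour sample.
#'
#' @param tracks data.frame with track_id, frame, x_um, y_um.
#' @param profile a [CurvatureProfile-class] of the nuclear contour (a bare
#'   contour is rejected: the curvature profile supplies rEq).
#' @param bandPx analysis band width in pixels (default 5).
#' @param pixelSize pixel size in um (default 0.145).
#' @param touchTol distance (um) within which a molecule counts as stopped
#'   at the envelope.
#' @return data.frame with track_id, frame, x_um, y_um, rEq, direction
#'   ("in"/"out"), crossed.
#' @export
classifyCrossings <- function(tracks, profile, bandPx = 5L,
                              pixelSize = 0.145, touchTol = 1e-6) {
  if (is(profile, "NuclearContour"))
    stop("no curvature profile attached: pass splineCurvature(contour)")
  stopifnot(is(profile, "CurvatureProfile"))
  bandUm <- bandPx * pixelSize
  ord <- order(tracks$track_id, tracks$frame)
  tr <- tracks[ord, ]
  pts <- cbind(tr$x_um, tr$y_um)
  d <- signedDistance(profile@contour, pts)
  n <- nrow(tr)
  samePair <- tr$track_id[-n] == tr$track_id[-1]
  d1 <- d[-n]; d2 <- d[-1]
  outside1 <- d1 > touchTol | abs(d1) <= touchTol
  inBand1 <- outside1 & d1 <= bandUm
  inward <- samePair & inBand1 & (d2 < -touchTol | abs(d2) <= touchTol)
  crossedIn <- d2 < -touchTol
  insideBand1 <- d1 < -touchTol & -d1 <= bandUm
  outward <- samePair & insideBand1 & d2 > touchTol
  sel <- which(inward | outward)
  if (!length(sel))
    return(data.frame(track_id = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(), rEq = numeric(),
                      direction = character(), crossed = logical()))
  coords <- profileCoordinates(profile)
  ni <- nearestContourIndex(coords, pts[sel, , drop = FALSE])
  data.frame(track_id = tr$track_id[sel], frame = tr$frame[sel],
             x_um = tr$x_um[sel], y_um = tr$y_um[sel],
             rEq = profile@rEq[ni],
             direction = ifelse(inward[sel], "in", "out"),
             crossed = ifelse(inward[sel], crossedIn[sel], TRUE))
}

#' Crossing fraction binned by curvature radius
#'
#' Bins inward approach events into equal-count bins over the curvature
#' radius rEq and reports the per-bin crossing fraction with its binomial
#' standard error.
#'
#' @param events data.frame from [classifyCrossings()] (inward events are
#'   selected automatically) or any data.frame with rEq and crossed.
#' @param nBins number of equal-count bins (default 8; enough bins keep the
#'   downstream weighted t-test on the slope calibrated).
#' @return data.frame with rEq (bin mean), fraction, se, n.
#' @export
crossingRatioVsRadius <- function(events, nBins = 8L) {
  if ("direction" %in% names(events))
    events <- events[events$direction == "in", , drop = FALSE]
  if (!nrow(events)) stop("no inward approach events")
  br <- unique(quantile(events$rEq, probs = seq(0, 1, length.out = nBins + 1L),
                        names = FALSE))
  if (length(br) < 3L)
    stop("events collapse into one rEq bin; use fewer bins")
  bin <- cut(events$rEq, breaks = br, include.lowest = TRUE, labels = FALSE)
  n <- tabulate(bin, nbins = length(br) - 1L)
  x <- vapply(seq_along(n), function(b) sum(events$crossed[bin == b]),
              numeric(1))
  p <- x / n
  pse <- (x + 0.5) / (n + 1)  # continuity-shifted for a nonzero SE
  se <- sqrt(pse * (1 - pse) / n)
  data.frame(rEq = vapply(seq_along(n), function(b)
    mean(events$rEq[bin == b]), numeric(1)),
    fraction = p, se = se, n = n)
}

#' Weighted linear fit of crossing fraction versus curvature radius
#'
#' Weighted least squares of the per-bin crossing fraction on the bin's
#' mean curvature radius (weights 1/SE^2), with a two-sided t-test on the
#' slope being zero. When the underlying events are supplied, a permutation
#' p-value (shuffling crossed labels across events, recomputing binned
#' fractions and slope) is reported as a distribution-free check.
#'
#' @param table data.frame from [crossingRatioVsRadius()].
#' @param events optional events data.frame to enable the permutation test.
#' @param nPerm number of label permutations (default 9999; set 0 to skip).
#' @return list with alpha (slope), beta (intercept), se, tValue, df,
#'   pValue, pPermutation, and the input table.
#' @export
fitCrossingSlope <- function(table, events = NULL, nPerm = 9999L) {
  if (nrow(table) < 3L) stop("need at least 3 bins to fit a slope")
  if (var(table$fraction) == 0)
    stop("zero-variance crossing fraction; slope undefined")
  w <- 1 / table$se^2
  fit <- lm(fraction ~ rEq, data = table, weights = w)
  sm <- summary(fit)
  alpha <- unname(coef(fit)[2]); beta <- unname(coef(fit)[1])
  seA <- sm$coefficients[2, 2]
  tv <- sm$coefficients[2, 3]
  pv <- sm$coefficients[2, 4]
  pPerm <- NA_real_
  if (!is.null(events) && nPerm > 0) {
    if ("direction" %in% names(events))
      events <- events[events$direction == "in", , drop = FALSE]
    br <- unique(quantile(events$rEq,
                          probs = seq(0, 1, length.out = nrow(table) + 1L),
                          names = FALSE))
    bin <- cut(events$rEq, breaks = br, include.lowest = TRUE,
               labels = FALSE)
    n <- tabulate(bin, nbins = length(br) - 1L)
    x <- table$rEq
    xw <- sum(w * x) / sum(w)
    hat <- w * (x - xw) / sum(w * (x - xw)^2)  # slope = sum(hat * fraction)
    lab <- as.numeric(events$crossed)
    slopes <- replicate(nPerm, {
      f <- rowsum(sample(lab), bin)[, 1] / n
      sum(hat * f)
    })
    pPerm <- (1 + sum(abs(slopes) >= abs(alpha))) / (nPerm + 1)
  }
  list(alpha = alpha, beta = beta, se = seA, tValue = tv,
       df = nrow(table) - 2L, pValue = pv, pPermutation = pPerm,
       table = table)
}
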