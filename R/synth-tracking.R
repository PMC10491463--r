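#' Synthetic single-molecule tracking data
#'
#' Generators for single-molecule movies near a nuclear contour with a
#' curvature-dependent translocation probability. Molecules diffuse with
#' isotropic Brownian steps; a step proposed from the cytosol into the
#' nucleus is an approach event: it succeeds with probability
#' \code{pCross(rEq)} evaluated at the nearest contour sample, otherwise
#' the molecule is stopped at the nuclear envelope (its position is set to
#' the nearest boundary point), which is how a rejected molecule presents
#' in the data. Ground-truth labels are recorded per approach.
#'
#' @name synthetic-tracking
NULL

# Outward unit normals at curvature-profile samples; contours here are
# star-shaped (ellipses), so the radial direction from the centroid is used.
.outwardNormals <- function(coords) {
  cx <- mean(coords[, 1]); cy <- mean(coords[, 2])
  dx <- coords[, 1] - cx; dy <- coords[, 2] - cy
  nr <- sqrt(dx^2 + dy^2)
  cbind(dx / nr, dy / nr)
}

#' Simulate isolated approach events at a nuclear contour
#'
#' Draws \code{nEvents} two-frame tracks, each an approach: the first
#' position sits in the analysis band outside the nucleus, the proposed
#' step ends inside, and the attempt succeeds with probability
#' \code{pCross(rEq)} at the nearest contour sample (rejected molecules are
#' stopped at the envelope). This isolates the crossing statistics from
#' free-diffusion dwell structure and is the fast path for calibration
#' studies.
#'
#' @param contour a [NuclearContour-class] (star-shaped).
#' @param nEvents number of approach events.
#' @param pCross function of the curvature radius rEq (um) returning a
#'   probability, or a single number for a curvature-independent
#'   probability.
#' @param bandPx analysis band width in pixels (default 5).
#' @param pixelSize pixel size in um (default 0.145).
#' @param frameIntervalS frame interval in seconds (default 0.010).
#' @param nProfileSamples curvature-profile resolution.
#' @param seed integer seed.
#' @return list with \code{tracks} (data.frame track_id, frame, x_um, y_um),
#'   \code{events} (ground-truth labels with true rEq), \code{contour},
#'   \code{profile} and \code{truth}.
#' @export
makeApproachEvents <- function(contour, nEvents = 2000L, pCross = 0.5,
                               bandPx = 5L, pixelSize = 0.145,
                               frameIntervalS = 0.010,
                               nProfileSamples = 400L, seed = 1L) {
  stopifnot(is(contour, "NuclearContour"), nEvents >= 1L)
  if (is.numeric(pCross)) {
    p0 <- pCross
    pCross <- function(rEq) rep(p0, length(rEq))
  }
  set.seed(seed)
  profile <- splineCurvature(contour, nSamples = nProfileSamples)
  coords <- profileCoordinates(profile)
  normals <- .outwardNormals(coords)
  bandUm <- bandPx * pixelSize
  idx <- sample.int(nrow(coords), nEvents, replace = TRUE)
  startOff <- runif(nEvents, 0.05, 0.95) * bandUm
  depth <- runif(nEvents, 0.05, 0.5)
  sx <- coords[idx, 1] + normals[idx, 1] * startOff
  sy <- coords[idx, 2] + normals[idx, 2] * startOff
  rEq <- profile@rEq[idx]
  p <- pmin(pmax(pCross(rEq), 0), 1)
  crossed <- runif(nEvents) < p
  # rejected molecules are stopped at the envelope: exactly on the contour
  # polygon, where the classifier sees zero signed distance
  stopped <- .projectToPolygon(contour, coords[idx, , drop = FALSE])
  ex <- ifelse(crossed, coords[idx, 1] - normals[idx, 1] * depth, stopped[, 1])
  ey <- ifelse(crossed, coords[idx, 2] - normals[idx, 2] * depth, stopped[, 2])
  tracks <- data.frame(
    track_id = rep(seq_len(nEvents), each = 2L),
    frame = rep(c(1L, 2L), nEvents),
    x_um = as.vector(rbind(sx, ex)),
    y_um = as.vector(rbind(sy, ey)))
  events <- data.frame(track_id = seq_len(nEvents), frame = 1L,
                       x_um = sx, y_um = sy, rEq = rEq, crossed = crossed)
  list(tracks = tracks, events = events, contour = contour,
       profile = profile,
       truth = list(bandPx = bandPx, pixelSize = pixelSize,
                    frameIntervalS = frameIntervalS, seed = seed))
}

#' Simulate a single-molecule tracking movie
#'
#' Free Brownian diffusion of \code{nMolecules} molecules in a rectangular
#' field of view containing a nuclear contour, with curvature-dependent
#' translocation at the envelope (see [synthetic-tracking]). Per-frame
#' displacements are Gaussian with sd \code{sqrt(2 D dt)} per axis;
#' field-of-view boundaries reflect. Optionally renders diffraction-limited
#' spot images for the detection/linking stages.
#'
#' @inheritParams makeApproachEvents
#' @param diffusionCoeff diffusion coefficient D in um^2/s.
#' @param nMolecules,nFrames simulation size (nFrames >= 2).
#' @param fovUm length-2 field of view (um); defaults to the contour's
#'   bounding box plus 4 um.
#' @param render logical; also return rendered frames (array x, y, t).
#' @param fwhmUm rendered spot FWHM in um (default 1, the detection
#'   diameter).
#' @param readSd additive Gaussian noise sd for rendered frames.
#' @return list with \code{tracks}, \code{events} (ground-truth approach
#'   labels), \code{frames} (array or NULL), \code{contour}, \code{profile},
#'   \code{truth}.
#' @export
makeTrackingMovie <- function(contour, diffusionCoeff = 2, pCross = 0.5,
                              nMolecules = 100L, nFrames = 100L,
                              frameIntervalS = 0.010, pixelSize = 0.145,
                              bandPx = 5L, fovUm = NULL,
                              nProfileSamples = 400L, render = FALSE,
                              fwhmUm = 1, readSd = 0, seed = 1L) {
  stopifnot(is(contour, "NuclearContour"), nFrames >= 2L, nMolecules >= 1L)
  if (is.numeric(pCross)) {
    p0 <- pCross
    pCross <- function(rEq) rep(p0, length(rEq))
  }
  set.seed(seed)
  profile <- splineCurvature(contour, nSamples = nProfileSamples)
  coords <- profileCoordinates(profile)
  if (is.null(fovUm)) {
    fovUm <- c(diff(range(contour@x)), diff(range(contour@y))) + 8
  }
  orig <- c(mean(range(contour@x)), mean(range(contour@y))) - fovUm / 2
  sdStep <- sqrt(2 * diffusionCoeff * frameIntervalS)
  # start molecules outside the nucleus, uniform over the FOV
  pos <- matrix(NA_real_, nMolecules, 2)
  filled <- 0L
  while (filled < nMolecules) {
    cand <- cbind(orig[1] + runif(nMolecules) * fovUm[1],
                  orig[2] + runif(nMolecules) * fovUm[2])
    keep <- signedDistance(contour, cand) > 0
    take <- min(sum(keep), nMolecules - filled)
    if (take > 0) {
      pos[filled + seq_len(take), ] <- cand[keep, , drop = FALSE][seq_len(take), ]
      filled <- filled + take
    }
  }
  X <- matrix(NA_real_, nMolecules, nFrames)
  Y <- matrix(NA_real_, nMolecules, nFrames)
  X[, 1] <- pos[, 1]; Y[, 1] <- pos[, 2]
  dCur <- signedDistance(contour, pos)
  ev <- vector("list", nFrames)
  for (f in 2L:nFrames) {
    prop <- pos + matrix(rnorm(2L * nMolecules, sd = sdStep), ncol = 2)
    # reflect at FOV boundaries
    for (k in 1:2) {
      over <- prop[, k] - orig[k]
      over <- abs(over)
      over <- fovUm[k] - abs(fovUm[k] - over %% (2 * fovUm[k]))
      prop[, k] <- orig[k] + fovUm[k] - over
    }
    dProp <- signedDistance(contour, prop)
    # start >= 0: molecules stopped at the envelope re-attempt on the next
    # inward proposal, as the classifier also sees them as outside
    attempt <- which(dCur >= 0 & dProp < 0)
    if (length(attempt)) {
      ni <- nearestContourIndex(coords, pos[attempt, , drop = FALSE])
      rEq <- profile@rEq[ni]
      p <- pmin(pmax(pCross(rEq), 0), 1)
      crossed <- runif(length(attempt)) < p
      stopIdx <- attempt[!crossed]
      if (length(stopIdx)) {
        stopped <- .projectToPolygon(contour,
                                     pos[stopIdx, , drop = FALSE])
        prop[stopIdx, ] <- stopped
        dProp[stopIdx] <- 0
      }
      inBand <- dCur[attempt] <= bandPx * pixelSize
      ev[[f]] <- data.frame(track_id = attempt, frame = f - 1L,
                            x_um = pos[attempt, 1], y_um = pos[attempt, 2],
                            rEq = rEq, crossed = crossed, inBand = inBand)
    }
    pos <- prop
    dCur <- dProp
    X[, f] <- pos[, 1]; Y[, f] <- pos[, 2]
  }
  events <- if (any(!vapply(ev, is.null, logical(1))))
    do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  else data.frame(track_id = integer(), frame = integer(), x_um = numeric(),
                  y_um = numeric(), rEq = numeric(), crossed = logical(),
                  inBand = logical())
  tracks <- data.frame(
    track_id = rep(seq_len(nMolecules), each = nFrames),
    frame = rep(seq_len(nFrames), nMolecules),
    x_um = as.vector(t(X)), y_um = as.vector(t(Y)))
  frames <- NULL
  if (render)
    frames <- renderSpotFrames(tracks, fovUm = fovUm, originUm = orig,
                               pixelSize = pixelSize, fwhmUm = fwhmUm,
                               readSd = readSd)
  list(tracks = tracks, events = events, frames = frames, contour = contour,
       profile = profile,
       truth = list(diffusionCoeff = diffusionCoeff,
                    frameIntervalS = frameIntervalS, pixelSize = pixelSize,
                    bandPx = bandPx, fovUm = fovUm, originUm = orig,
                    seed = seed))
}

#' Render diffraction-limited spot frames from tracks
#'
#' Splats each localization as a 2D Gaussian with the stated FWHM (1 um by
#' default, matching the detection diameter at 145 nm/px).
#'
#' @param tracks data.frame with track_id, frame, x_um, y_um.
#' @param fovUm length-2 field of view in um.
#' @param originUm length-2 origin of the field of view in um.
#' @param pixelSize pixel size in um.
#' @param fwhmUm spot full width at half maximum in um.
#' @param intensity peak intensity per spot.
#' @param readSd additive Gaussian noise sd.
#' @return numeric array \code{[x, y, frame]}.
#' @export
renderSpotFrames <- function(tracks, fovUm, originUm = c(0, 0),
                             pixelSize = 0.145, fwhmUm = 1, intensity = 1,
                             readSd = 0) {
  sigmaPx <- fwhmUm / (2 * sqrt(2 * log(2))) / pixelSize
  nx <- as.integer(ceiling(fovUm[1] / pixelSize)) + 1L
  ny <- as.integer(ceiling(fovUm[2] / pixelSize)) + 1L
  nFrames <- max(tracks$frame)
  out <- array(0, dim = c(nx, ny, nFrames))
  k <- as.integer(ceiling(4 * sigmaPx))
  for (f in seq_len(nFrames)) {
    sel <- tracks$frame == f
    if (!any(sel)) next
    xs <- (tracks$x_um[sel] - originUm[1]) / pixelSize
    ys <- (tracks$y_um[sel] - originUm[2]) / pixelSize
    pl <- out[, , f]
    for (j in seq_along(xs)) {
      cxi <- round(xs[j]) + 1L; cyi <- round(ys[j]) + 1L
      if (cxi + k < 1L || cxi - k > nx || cyi + k < 1L || cyi - k > ny) next
      xi <- max(1L, cxi - k):min(nx, cxi + k)
      yi <- max(1L, cyi - k):min(ny, cyi + k)
      dx2 <- ((xi - 1) - xs[j])^2
      dy2 <- ((yi - 1) - ys[j])^2
      pl[xi, yi] <- pl[xi, yi] +
        intensity * exp(-outer(dx2, dy2, "+") / (2 * sigmaPx^2))
    }
    out[, , f] <- pl
  }
  if (readSd > 0) out[] <- out + rnorm(length(out), sd = readSd)
  out
}
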