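#' Synthetic image generators with known ground truth
#'
#' The generators in this file emulate the fluorescence data the analysis
#' operates on: ellipsoidal nuclei in z-stacks, lamin rim planes with a
#' controllable two-segment major-axis profile, chromatin planes with
#' controllable clustering, oriented actin fibers, and paired channels with
#' region-controlled local correlation. Every generator takes an integer
#' seed and is byte-identical for a fixed seed. All images are numeric
#' matrices/arrays indexed \code{[x, y(, z)]} with pixel centres at 0-based
#' integer multiples of the pixel size.
#'
#' @name synthetic-images
NULL

# Additive Gaussian read noise plus (optional) Poisson shot noise scaled by
# intensity. shotScale is the photon count per intensity unit; 0 disables.
.imageNoise <- function(img, readSd = 0, shotScale = 0) {
  if (shotScale > 0) {
    lam <- pmax(img, 0) * shotScale
    img <- img + (rpois(length(img), lam) - lam) / shotScale
  }
  if (readSd > 0) img <- img + rnorm(length(img), sd = readSd)
  img
}

#' Synthetic ellipsoidal nucleus z-stack
#'
#' Renders a binary-plus-noise ellipsoidal nucleus centred in a 3D volume,
#' emulating a Hoechst-stained nucleus whose semiaxes are later measured
#' from orthogonal projections.
#'
#' @param semiaxes length-3 numeric (a, b, c) in micrometres, a along x.
#' @param voxelSize length-3 numeric (dx, dy, dz) in micrometres.
#' @param marginUm empty margin around the nucleus (um).
#' @param fovUm optional length-3 field of view (um); semiaxes that do not
#'   fit raise an error.
#' @param interior intensity inside the nucleus (background is 0).
#' @param psfSigmaPx isotropic Gaussian blur applied per z-slice, in pixels.
#' @param readSd,shotScale noise parameters, see Details in
#'   [synthetic-images].
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with \code{stack} (3D array) and \code{truth} (generator
#'   parameters).
#' @export
makeNucleusStack <- function(semiaxes, voxelSize = c(0.2, 0.2, 0.5),
                             marginUm = 1, fovUm = NULL, interior = 1,
                             psfSigmaPx = 0, readSd = 0, shotScale = 0,
                             seed = 1L) {
  stopifnot(length(semiaxes) == 3L, all(semiaxes > 0),
            length(voxelSize) == 3L, all(voxelSize > 0))
  ext <- 2 * (semiaxes + marginUm)
  if (!is.null(fovUm) && any(2 * semiaxes > fovUm))
    stop(sprintf("semiaxes (%s um) exceed the field of view (%s um)",
                 paste(signif(semiaxes, 3), collapse = ", "),
                 paste(signif(fovUm, 3), collapse = ", ")))
  set.seed(seed)
  dims <- pmax(as.integer(ceiling(ext / voxelSize)) + 1L, 4L)
  ctr <- (dims - 1L) / 2 * voxelSize
  gx <- ((seq_len(dims[1]) - 1) * voxelSize[1] - ctr[1]) / semiaxes[1]
  gy <- ((seq_len(dims[2]) - 1) * voxelSize[2] - ctr[2]) / semiaxes[2]
  gz <- ((seq_len(dims[3]) - 1) * voxelSize[3] - ctr[3]) / semiaxes[3]
  q <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  stack <- array(ifelse(q <= 1, interior, 0), dim = dims)
  if (psfSigmaPx > 0)
    for (k in seq_len(dims[3]))
      stack[, , k] <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(stack[, , k]), sigma = psfSigmaPx))
  if (readSd > 0 || shotScale > 0)
    stack[] <- .imageNoise(stack, readSd, shotScale)
  list(stack = stack,
       truth = list(semiaxes = semiaxes, voxelSize = voxelSize,
                    interior = interior, psfSigmaPx = psfSigmaPx,
                    readSd = readSd, shotScale = shotScale, seed = seed))
}

#' Synthetic lamin / phospho-lamin equatorial planes
#'
#' Renders an elliptical nucleus whose normalized major-axis intensity
#' profile is piecewise linear: value 1 at the nuclear edge, declining with
#' slope \code{edgeSlope} (per unit normalized diameter) up to
#' \code{breakpointFrac}, then a second line reaching \code{interiorLevel}
#' at the opposite edge. An optional radially symmetric rim
#' (\code{rimBoost}) brightens the edge band all around the boundary, as
#' the lamina does at the equatorial plane. A companion phospho channel is
#' a uniform disk. Multiplicative texture with coefficient of variation
#' \code{edgeCv} is applied to the edge band of both channels.
#'
#' @param radiusUm nuclear semi-minor axis (um); the semi-major axis is
#'   \code{aspect} times larger, along x.
#' @param breakpointFrac two-segment breakpoint in (0, 1), as a fraction of
#'   the normalized major-axis diameter; 100x this value is the lamina
#'   occupancy.
#' @param edgeSlope slope of the edge segment (negative for a declining
#'   rim), per unit normalized diameter.
#' @param interiorLevel normalized intensity at the far edge of the
#'   interior segment.
#' @param edgeCv coefficient of variation of the multiplicative edge-band
#'   texture (0 for none).
#' @param rimBoost relative brightening of the edge band, uniform around
#'   the boundary (0 for none).
#' @param aspect major/minor axis ratio of the nucleus (default 1.25).
#' @param pixelSize pixel pitch (um), default 0.145.
#' @param bandPx edge-band width in pixels (default 5).
#' @param readSd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with \code{lamin}, \code{phospho} (matrices),
#'   \code{contour} (a [NuclearContour-class]) and \code{truth}.
#' @export
makeLaminPlanes <- function(radiusUm = 6, breakpointFrac = 0.21,
                            edgeSlope = -0.765, interiorLevel = 0.75,
                            edgeCv = 0, rimBoost = 0, aspect = 1.25,
                            pixelSize = 0.145, bandPx = 5L,
                            readSd = 0, seed = 1L) {
  if (!(breakpointFrac > 0 && breakpointFrac < 1))
    stop("breakpointFrac must lie in (0, 1)")
  stopifnot(radiusUm > 0, aspect >= 1)
  set.seed(seed)
  a <- radiusUm * aspect; b <- radiusUm
  marginUm <- 1
  nx <- as.integer(ceiling(2 * (a + marginUm) / pixelSize)) + 1L
  ny <- as.integer(ceiling(2 * (b + marginUm) / pixelSize)) + 1L
  ctrx <- (nx - 1) / 2 * pixelSize
  ctry <- (ny - 1) / 2 * pixelSize
  X <- matrix((seq_len(nx) - 1) * pixelSize, nx, ny) - ctrx
  Y <- matrix((seq_len(ny) - 1) * pixelSize, nx, ny, byrow = TRUE) - ctry
  q <- sqrt((X / a)^2 + (Y / b)^2)
  inside <- q <= 1
  # normalized position along the major (x) axis, 0 at the left edge
  p <- (X + a) / (2 * a)
  vb <- 1 + edgeSlope * breakpointFrac
  innerSlope <- (interiorLevel - vb) / (1 - breakpointFrac)
  prof <- ifelse(p < breakpointFrac, 1 + edgeSlope * p,
                 vb + innerSlope * (p - breakpointFrac))
  lamin <- ifelse(inside, pmax(prof, 0), 0)
  phospho <- ifelse(inside, 0.5, 0)
  # edge band: within bandPx of the boundary (approximated radially)
  band <- inside & (1 - q) * b <= bandPx * pixelSize
  if (rimBoost > 0) lamin[band] <- lamin[band] * (1 + rimBoost)
  if (edgeCv > 0) {
    lamin[band] <- lamin[band] * pmax(1 + edgeCv * rnorm(sum(band)), 0)
    phospho[band] <- phospho[band] * pmax(1 + edgeCv * rnorm(sum(band)), 0)
  }
  if (readSd > 0) {
    lamin[] <- .imageNoise(lamin, readSd)
    phospho[] <- .imageNoise(phospho, readSd)
  }
  contour <- ellipseContour(a, b, n = 256L, center = c(ctrx, ctry))
  list(lamin = lamin, phospho = phospho, contour = contour,
       truth = list(radiusUm = radiusUm, aspect = aspect,
                    breakpointFrac = breakpointFrac,
                    edgeSlope = edgeSlope, interiorLevel = interiorLevel,
                    edgeCv = edgeCv, rimBoost = rimBoost,
                    pixelSize = pixelSize, bandPx = bandPx,
                    readSd = readSd, seed = seed))
}

#' Synthetic chromatin plane with controllable clustering
#'
#' Renders a nuclear disk with Gaussian blob texture whose line-ROI
#' coefficient of variation increases monotonically with
#' \code{clusterStrength} (0 gives a uniform disk at the noise floor).
#'
#' @param clusterStrength nonnegative blob amplitude relative to the base
#'   level.
#' @param radiusUm nuclear radius (um).
#' @param pixelSize pixel pitch (um).
#' @param nBlobs number of chromatin clusters.
#' @param blobSigmaUm cluster size (um).
#' @param readSd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with \code{plane}, \code{contour} and \code{truth}.
#' @export
makeChromatinPlane <- function(clusterStrength, radiusUm = 7,
                               pixelSize = 0.145, nBlobs = 60L,
                               blobSigmaUm = 0.5, readSd = 0.01, seed = 1L) {
  stopifnot(clusterStrength >= 0, radiusUm > 0)
  set.seed(seed)
  marginUm <- 1
  n <- as.integer(ceiling(2 * (radiusUm + marginUm) / pixelSize)) + 1L
  ctr <- (n - 1) / 2 * pixelSize
  px <- (seq_len(n) - 1) * pixelSize
  X <- matrix(px, n, n) - ctr
  Y <- matrix(px, n, n, byrow = TRUE) - ctr
  r2 <- X^2 + Y^2
  inside <- r2 <= radiusUm^2
  plane <- ifelse(inside, 0.5, 0)
  if (clusterStrength > 0 && nBlobs > 0) {
    th <- runif(nBlobs, 0, 2 * pi)
    rad <- radiusUm * sqrt(runif(nBlobs)) * 0.9
    bx <- rad * cos(th); by <- rad * sin(th)
    amp <- 0.5 * clusterStrength * runif(nBlobs, 0.5, 1)
    for (i in seq_len(nBlobs))
      plane <- plane + amp[i] *
        exp(-((X - bx[i])^2 + (Y - by[i])^2) / (2 * blobSigmaUm^2))
    plane[!inside] <- 0
  }
  if (readSd > 0) plane[] <- .imageNoise(plane, readSd)
  contour <- ellipseContour(radiusUm, radiusUm, n = 256L,
                            center = c(ctr, ctr))
  list(plane = plane, contour = contour,
       truth = list(clusterStrength = clusterStrength, radiusUm = radiusUm,
                    pixelSize = pixelSize, nBlobs = nBlobs,
                    blobSigmaUm = blobSigmaUm, readSd = readSd, seed = seed))
}

#' Synthetic oriented-fiber image
#'
#' Draws straight fibers with orientations sampled from a wrapped normal
#' distribution (or uniform on -90..90 when \code{thetaSdDeg} is infinite),
#' emulating actin stress fibers for directionality analysis. Angles follow
#' the mathematical convention: degrees from the +x axis, y upward.
#'
#' @param thetaMeanDeg mean orientation in degrees, in [-90, 90].
#' @param thetaSdDeg orientation spread in degrees; \code{Inf} for
#'   isotropic fibers.
#' @param nFibers number of fibers (0 gives background only).
#' @param sizePx image side length in pixels.
#' @param fiberLengthPx fiber length in pixels.
#' @param fiberSigmaPx Gaussian cross-section of a fiber in pixels.
#' @param readSd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with \code{plane} and \code{truth} (including the sampled
#'   angles).
#' @export
makeFiberImage <- function(thetaMeanDeg = 0, thetaSdDeg = 15, nFibers = 80L,
                           sizePx = 192L, fiberLengthPx = 60,
                           fiberSigmaPx = 1, readSd = 0.01, seed = 1L) {
  stopifnot(thetaMeanDeg >= -90, thetaMeanDeg <= 90)
  set.seed(seed)
  plane <- matrix(0, sizePx, sizePx)
  angles <- numeric(0)
  if (nFibers > 0) {
    angles <- if (is.infinite(thetaSdDeg)) runif(nFibers, -90, 90)
              else thetaMeanDeg + thetaSdDeg * rnorm(nFibers)
    angles <- ((angles + 90) %% 180) - 90
    cx <- runif(nFibers, 0.1, 0.9) * (sizePx - 1)
    cy <- runif(nFibers, 0.1, 0.9) * (sizePx - 1)
    half <- fiberLengthPx / 2
    ts <- seq(-half, half, by = 0.5)
    k <- 3L  # stamp half-width in px
    for (i in seq_len(nFibers)) {
      th <- angles[i] * pi / 180
      xs <- cx[i] + ts * cos(th)
      ys <- cy[i] + ts * sin(th)
      for (j in seq_along(ts)) {
        cxi <- round(xs[j]) + 1L; cyi <- round(ys[j]) + 1L
        if (cxi + k < 1L || cxi - k > sizePx ||
            cyi + k < 1L || cyi - k > sizePx) next
        xi <- max(1L, cxi - k):min(sizePx, cxi + k)
        yi <- max(1L, cyi - k):min(sizePx, cyi + k)
        dx2 <- ((xi - 1) - xs[j])^2
        dy2 <- ((yi - 1) - ys[j])^2
        plane[xi, yi] <- plane[xi, yi] +
          0.1 * exp(-outer(dx2, dy2, "+") / (2 * fiberSigmaPx^2))
      }
    }
    plane <- pmin(plane, 1)
  }
  if (readSd > 0) plane[] <- .imageNoise(plane, readSd)
  list(plane = plane,
       truth = list(thetaMeanDeg = thetaMeanDeg, thetaSdDeg = thetaSdDeg,
                    nFibers = nFibers, angles = angles, sizePx = sizePx,
                    readSd = readSd, seed = seed))
}

#' Synthetic image pair with region-controlled local correlation
#'
#' Builds two noise images over a circular nucleus such that the local
#' Pearson correlation map exceeds +0.4 in a requested fraction of the
#' edge band and of the interior. Correlated zones are contiguous angular
#' sectors where the second channel copies the first; elsewhere the
#' channels are independent.
#'
#' @param edgeCorrFrac,interiorCorrFrac fractions in [0, 1] of each region
#'   to correlate.
#' @param sizePx image side length in pixels.
#' @param radiusPx nuclear radius in pixels.
#' @param bandPx edge-band width in pixels; the default, (1 - 1/sqrt(2))
#'   times the radius, makes the band and the interior equal in area, so a
#'   per-region correlated fraction equals that region's share of all
#'   correlating pixels.
#' @param seed integer seed.
#' @return list with \code{a}, \code{b} (matrices), \code{edgeMask},
#'   \code{interiorMask}, \code{contour}, recommended analysis
#'   \code{windowPx}, and \code{truth}.
#' @export
makeCorrelationPair <- function(edgeCorrFrac, interiorCorrFrac,
                                sizePx = 192L, radiusPx = 70,
                                bandPx = (1 - 1 / sqrt(2)) * radiusPx,
                                seed = 1L) {
  stopifnot(edgeCorrFrac >= 0, edgeCorrFrac <= 1,
            interiorCorrFrac >= 0, interiorCorrFrac <= 1)
  set.seed(seed)
  ctr <- (sizePx - 1) / 2
  ix <- matrix(seq_len(sizePx) - 1, sizePx, sizePx)
  iy <- matrix(seq_len(sizePx) - 1, sizePx, sizePx, byrow = TRUE)
  r <- sqrt((ix - ctr)^2 + (iy - ctr)^2)
  theta <- atan2(iy - ctr, ix - ctr)  # (-pi, pi]
  inside <- r <= radiusPx
  edgeMask <- inside & (radiusPx - r) <= bandPx
  interiorMask <- inside & !edgeMask
  a <- matrix(rnorm(sizePx^2), sizePx, sizePx)
  b <- matrix(rnorm(sizePx^2), sizePx, sizePx)
  corrMask <- matrix(FALSE, sizePx, sizePx)
  sector <- function(mask, frac) {
    if (frac <= 0) return(mask & FALSE)
    # contiguous angular sector covering the requested fraction of the region
    qs <- quantile(theta[mask], probs = frac, names = FALSE)
    mask & theta <= qs
  }
  corrMask <- corrMask | sector(edgeMask, edgeCorrFrac) |
    sector(interiorMask, interiorCorrFrac)
  b[corrMask] <- a[corrMask]
  contour <- ellipseContour(radiusPx, radiusPx, n = 256L, center = c(ctr, ctr))
  list(a = a, b = b, edgeMask = edgeMask, interiorMask = interiorMask,
       contour = contour, windowPx = 9L,
       truth = list(edgeCorrFrac = edgeCorrFrac,
                    interiorCorrFrac = interiorCorrFrac, sizePx = sizePx,
                    radiusPx = radiusPx, bandPx = bandPx, seed = seed))
}
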