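#' Coefficient of variation of an intensity sample
#'
#' CV = sd / mean with the sample (n-1) standard deviation; a dimensionless
#' homogeneity metric (0 for a perfectly uniform sample), invariant to
#' multiplicative intensity rescaling.
#'
#' @param intensities numeric vector, at least 2 samples with positive mean.
#' @return the coefficient of variation.
#' @examples
#' coefficientOfVariation(c(1, 2, 3))  # 0.5
#' @export
coefficientOfVariation <- function(intensities) {
  if (length(intensities) < 2L) stop("need at least 2 samples")
  m <- mean(intensities)
  if (m <= 0) stop("mean intensity must be positive")
  sd(intensities) / m
}

# Pixel mask of a polygon contour on an image grid (pixel centres at
# 0-based integer * pixelSize).
.contourMask <- function(plane, contour, pixelSize) {
  nx <- nrow(plane); ny <- ncol(plane)
  px <- rep((seq_len(nx) - 1) * pixelSize, times = ny)
  py <- rep((seq_len(ny) - 1) * pixelSize, each = nx)
  matrix(.pointInPolygon(px, py, contour@x, contour@y), nx, ny)
}

#' Coefficient of variation along a radial line ROI
#'
#' Samples the intensity at pixel pitch along a straight line from a point
#' on the nuclear edge toward the nuclear centre and returns the CV of the
#' sampled intensities. The line must stay inside the nucleus; an optional
#' avoidance mask (e.g. manually outlined nucleoli) invalidates lines that
#' touch it.
#'
#' @param plane numeric matrix \code{[x, y]}.
#' @param contour a [NuclearContour-class] in um.
#' @param inwardLengthUm length of the line ROI (um).
#' @param pixelSize pixel size (um).
#' @param startAngle direction from the centroid (radians) selecting the
#'   edge point where the line starts.
#' @param avoidMask optional logical matrix; TRUE pixels invalidate the ROI.
#' @return the CV of the line samples.
#' @export
linearRoiCV <- function(plane, contour, inwardLengthUm, pixelSize = 0.145,
                        startAngle = 0, avoidMask = NULL) {
  cx <- mean(contour@x); cy <- mean(contour@y)
  dirv <- c(cos(startAngle), sin(startAngle))
  # edge point: march from the centroid outward to the boundary
  lo <- 0; hi <- max(sqrt((contour@x - cx)^2 + (contour@y - cy)^2)) * 1.5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    p <- c(cx, cy) + mid * dirv
    if (signedDistance(contour, p) < 0) lo <- mid else hi <- mid
  }
  edge <- c(cx, cy) + lo * dirv
  # start one pixel inside the boundary so the rounded first sample cannot
  # fall on a background pixel
  ts <- seq(pixelSize, inwardLengthUm, by = pixelSize)
  xs <- edge[1] - ts * dirv[1]
  ys <- edge[2] - ts * dirv[2]
  if (any(signedDistance(contour, cbind(xs, ys)) > 0))
    stop("line ROI exits the nucleus; shorten inwardLengthUm")
  xi <- round(xs / pixelSize) + 1L
  yi <- round(ys / pixelSize) + 1L
  if (any(xi < 1 | xi > nrow(plane) | yi < 1 | yi > ncol(plane)))
    stop("line ROI exits the image")
  if (!is.null(avoidMask) && any(avoidMask[cbind(xi, yi)]))
    stop("line ROI crosses the avoidance mask")
  coefficientOfVariation(plane[cbind(xi, yi)])
}

#' Edge-band and eroded-interior masks for a nuclear plane
#'
#' The edge band is the set of nuclear pixels within \code{bandPx} pixels
#' of the contour; the interior is the nuclear region eroded by the same
#' band (the polygon interior at least bandPx from the border).
#'
#' @param plane numeric matrix (defines the grid).
#' @param contour a [NuclearContour-class].
#' @param bandPx band width in pixels (default 5, i.e. about 0.7 um at
#'   145 nm/px). Set \code{bandUm} instead to force a width in um.
#' @param pixelSize pixel size (um).
#' @param bandUm optional band width in um, overriding bandPx.
#' @return list of logical matrices \code{edge} and \code{interior}.
#' @export
nuclearRegionMasks <- function(plane, contour, bandPx = 5L,
                               pixelSize = 0.145, bandUm = NULL) {
  if (is.null(bandUm)) bandUm <- bandPx * pixelSize
  nx <- nrow(plane); ny <- ncol(plane)
  px <- rep((seq_len(nx) - 1) * pixelSize, times = ny)
  py <- rep((seq_len(ny) - 1) * pixelSize, each = nx)
  d <- matrix(signedDistance(contour, cbind(px, py)), nx, ny)
  list(edge = d <= 0 & d >= -bandUm, interior = d < -bandUm)
}

#' Edge-to-interior intensity ratio beta
#'
#' beta = mean intensity over the edge band / mean intensity over the
#' eroded interior; ~1 for a homogeneous distribution and >1 when the
#' protein accumulates at the nuclear rim.
#'
#' @inheritParams nuclearRegionMasks
#' @param masks optional precomputed result of [nuclearRegionMasks()].
#' @return the ratio beta.
#' @export
betaRatio <- function(plane, contour, bandPx = 5L, pixelSize = 0.145,
                      bandUm = NULL, masks = NULL) {
  if (is.null(masks))
    masks <- nuclearRegionMasks(plane, contour, bandPx, pixelSize, bandUm)
  if (!any(masks$edge) || !any(masks$interior))
    stop("empty edge or interior region")
  mi <- mean(plane[masks$interior])
  if (mi == 0) stop("zero interior mean intensity")
  mean(plane[masks$edge]) / mi
}

#' Normalized intensity profile along the nuclear major axis
#'
#' Draws a line ROI along the nuclear major axis (from the contour's
#' second-order moments) across the full nucleus, samples the intensity at
#' pixel pitch, normalizes the position to [0, 1] (diameter) and the
#' intensity to its maximum.
#'
#' @param plane numeric matrix \code{[x, y]}.
#' @param contour a [NuclearContour-class].
#' @param pixelSize pixel size (um).
#' @return an [IntensityProfile-class].
#' @export
majorAxisProfile <- function(plane, contour, pixelSize = 0.145) {
  mask <- .contourMask(plane, contour, pixelSize)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 10L) stop("degenerate contour: too few interior pixels")
  pts <- (idx - 1) * pixelSize
  cv <- cov(pts)
  ax <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  ctr <- colMeans(pts)
  proj <- as.vector((as.matrix(pts) - matrix(ctr, nrow(pts), 2,
                                             byrow = TRUE)) %*% ax)
  lo <- min(proj); hi <- max(proj)
  ts <- seq(lo, hi, by = pixelSize)
  xs <- ctr[1] + ts * ax[1]; ys <- ctr[2] + ts * ax[2]
  xi <- round(xs / pixelSize) + 1L
  yi <- round(ys / pixelSize) + 1L
  keep <- xi >= 1 & xi <= nrow(plane) & yi >= 1 & yi <= ncol(plane)
  keep[keep] <- mask[cbind(xi[keep], yi[keep])]
  ts <- ts[keep]
  I <- plane[cbind(xi[keep], yi[keep])]
  if (length(I) < 10L) stop("degenerate contour: profile too short")
  pos <- (ts - min(ts)) / (max(ts) - min(ts))
  # profile runs from the brighter edge inward, matching the convention
  # that the lamin rim peak sits at position 0
  if (which.max(I) > length(I) / 2) {
    pos <- rev(1 - pos); I <- rev(I)
  }
  new("IntensityProfile", position = pos, intensity = I / max(I))
}

#' Construct an intensity profile from raw samples
#'
#' @param position numeric positions (any increasing scale; rescaled to
#'   [0, 1]).
#' @param intensity numeric intensities (normalized to max 1).
#' @return an [IntensityProfile-class].
#' @export
intensityProfile <- function(position, intensity) {
  ord <- order(position)
  position <- position[ord]; intensity <- intensity[ord]
  pos <- (position - min(position)) / (max(position) - min(position))
  new("IntensityProfile", position = pos, intensity = intensity / max(intensity))
}

#' Two-segment linear fit with exhaustive breakpoint search
#'
#' Fits two least-squares lines to an edge-to-centre normalized profile,
#' choosing the breakpoint over all admissible sample positions (at least
#' 3 samples per segment) to minimize the total residual sum of squares.
#' The edge slope is the first segment's slope and the lamina occupancy is
#' 100 times the breakpoint position. When no breakpoint improves on a
#' single line by more than 1\\% of its RSS the profile is flagged
#' degenerate and the whole-profile slope is reported.
#'
#' @param profile an [IntensityProfile-class] with at least 10 samples.
#' @return a [TwoSegmentFit-class].
#' @export
twoSegmentFit <- function(profile) {
  stopifnot(is(profile, "IntensityProfile"))
  x <- profile@position; y <- profile@intensity
  n <- length(x)
  if (n < 10L) stop("need at least 10 profile samples")
  segRss <- function(xi, yi) {
    X <- cbind(1, xi)
    cf <- .lmFit(X, yi)
    r <- yi - X %*% cf
    list(rss = sum(r^2), slope = cf[2],
         r2 = 1 - sum(r^2) / max(sum((yi - mean(yi))^2), .Machine$double.eps))
  }
  whole <- segRss(x, y)
  cand <- 4:(n - 3)
  fits <- lapply(cand, function(bp)
    list(bp = bp, le = segRss(x[1:bp], y[1:bp]),
         ri = segRss(x[(bp + 1):n], y[(bp + 1):n])))
  rss <- vapply(fits, function(f) f$le$rss + f$ri$rss, numeric(1))
  bestRss <- min(rss)
  # a kink sample lies on both lines, so noiseless profiles tie (to
  # rounding) at the kink and one sample before it; take the rightmost
  # near-tie so the kink itself closes the edge segment
  tol <- max(1e-9 * whole$rss, 1e-18)
  best <- fits[[max(which(rss <= bestRss + tol))]]
  # numerically straight profiles (whole-line RSS at rounding level) are
  # degenerate regardless of the relative improvement
  improves <- whole$rss > 1e-16 * sum(y^2) && bestRss < 0.99 * whole$rss
  if (!improves) {
    return(new("TwoSegmentFit", edgeSlope = unname(whole$slope),
               breakpoint = NA_real_, occupancy = NA_real_,
               innerSlope = NA_real_, r2Edge = whole$r2, r2Inner = NA_real_,
               degenerate = TRUE))
  }
  bpPos <- x[best$bp]
  new("TwoSegmentFit", edgeSlope = unname(best$le$slope),
      breakpoint = bpPos, occupancy = 100 * bpPos,
      innerSlope = unname(best$ri$slope), r2Edge = best$le$r2,
      r2Inner = best$ri$r2, degenerate = FALSE)
}

.lmFit <- function(X, y) {
  qr.coef(qr(X), y)
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Mean intensity over the nuclear ROI divided by the mean over a
#' cytoplasmic ROI of comparable area.
#'
#' @param plane numeric matrix.
#' @param nuclearMask,cytoMask disjoint logical matrices.
#' @return the ratio.
#' @export
nucCytoRatio <- function(plane, nuclearMask, cytoMask) {
  if (any(nuclearMask & cytoMask)) stop("ROIs must be disjoint")
  if (!any(nuclearMask) || !any(cytoMask)) stop("empty ROI")
  aN <- sum(nuclearMask); aC <- sum(cytoMask)
  if (max(aN, aC) / min(aN, aC) > 2)
    warning("ROI areas differ by more than 2x; keep them similar")
  mC <- mean(plane[cytoMask])
  if (mC == 0) stop("zero cytoplasmic mean intensity")
  mean(plane[nuclearMask]) / mC
}
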