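#' Local Pearson correlation map between two channels
#'
#' Per-pixel Pearson correlation of two registered images computed over a
#' sliding square window; at the image border the window is truncated.
#' Pixels where either channel is constant within the window have no
#' defined correlation: they are set to 0 and flagged in
#' \code{undefinedMask}.
#'
#' @param a,b numeric matrices of equal dimension.
#' @param windowPx odd window side length >= 3 (default 5).
#' @param edgeMask,interiorMask optional disjoint logical region masks
#'   carried on the result (e.g. from [nuclearRegionMasks()]).
#' @return a [CorrelationMap-class].
#' @export
localCorrelationMap <- function(a, b, windowPx = 5L, edgeMask = NULL,
                                interiorMask = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  if (windowPx < 3L || windowPx %% 2L == 0L)
    stop("windowPx must be odd and >= 3")
  cnt <- .boxSum(matrix(1, nrow(a), ncol(a)), windowPx)
  sa <- .boxSum(a, windowPx); sb <- .boxSum(b, windowPx)
  saa <- .boxSum(a * a, windowPx); sbb <- .boxSum(b * b, windowPx)
  sab <- .boxSum(a * b, windowPx)
  ma <- sa / cnt; mb <- sb / cnt
  va <- saa / cnt - ma^2
  vb <- sbb / cnt - mb^2
  cab <- sab / cnt - ma * mb
  eps <- 1e-12
  undef <- va <= eps | vb <= eps
  r <- matrix(0, nrow(a), ncol(a))
  ok <- !undef
  r[ok] <- pmin(pmax(cab[ok] / sqrt(va[ok] * vb[ok]), -1), 1)
  if (is.null(edgeMask)) edgeMask <- matrix(FALSE, nrow(a), ncol(a))
  if (is.null(interiorMask)) interiorMask <- matrix(FALSE, nrow(a), ncol(a))
  new("CorrelationMap", values = r, edgeMask = edgeMask,
      interiorMask = interiorMask, undefinedMask = undef)
}

# Sliding-window sum with border truncation, via 2D cumulative sums.
.boxSum <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nx <- nrow(m); ny <- ncol(m)
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # cs[j, i] = sum over [1..i, 1..j]
  cs <- t(cs)
  P <- matrix(0, nx + 1L, ny + 1L)
  P[-1, -1] <- cs
  x1 <- pmax(seq_len(nx) - h, 1L); x2 <- pmin(seq_len(nx) + h, nx)
  y1 <- pmax(seq_len(ny) - h, 1L); y2 <- pmin(seq_len(ny) + h, ny)
  P[x2 + 1L, y2 + 1L] - P[x1, y2 + 1L] - P[x2 + 1L, y1] + P[x1, y1]
}

#' Threshold a correlation map
#'
#' Removes weak correlations: pixels with values strictly below \code{lo}
#' or strictly above \code{hi} survive; the closed interval [lo, hi]
#' (including the endpoints) is removed, as are undefined pixels.
#'
#' @param map a [CorrelationMap-class].
#' @param lo,hi removal interval endpoints (defaults -0.4 and +0.4).
#' @return logical matrix of surviving pixels.
#' @export
thresholdCorrelation <- function(map, lo = -0.4, hi = 0.4) {
  stopifnot(is(map, "CorrelationMap"))
  if (lo >= hi) stop("lo must be smaller than hi")
  (map@values < lo | map@values > hi) & !map@undefinedMask
}

#' Share of correlating pixels per nuclear region
#'
#' Among the surviving positively-correlating pixels that fall in the edge
#' band or the interior, returns the percentage in each region (the two
#' percentages sum to 100).
#'
#' @param map a [CorrelationMap-class] with region masks.
#' @param surviving logical matrix from [thresholdCorrelation()].
#' @return named numeric vector c(edge, interior), in percent.
#' @export
correlationFractionByRegion <- function(map, surviving) {
  stopifnot(is(map, "CorrelationMap"))
  pos <- surviving & map@values > 0
  nE <- sum(pos & map@edgeMask)
  nI <- sum(pos & map@interiorMask)
  if (nE + nI == 0L) stop("no surviving positively-correlating pixels")
  c(edge = 100 * nE / (nE + nI), interior = 100 * nI / (nE + nI))
}

#' Colocalization frequency as a function of nuclear curvature
#'
#' Assigns to every surviving edge-band pixel the curvature magnitude of
#' its nearest contour sample, builds the frequency distribution (percent
#' of pixels per bin) and fits a Gaussian.
#'
#' @param map a [CorrelationMap-class] with a nonempty edge mask.
#' @param surviving logical matrix from [thresholdCorrelation()].
#' @param profile a [CurvatureProfile-class] of the nuclear contour.
#' @param pixelSize pixel size in um (the map grid must match the contour
#'   coordinates).
#' @param binWidth histogram bin width in 1/um.
#' @return list with \code{mids}, \code{frequency} (percent) and \code{fit}
#'   (a [GaussianFit-class]; degenerate for near-uniform placement).
#' @export
colocalizationVsCurvature <- function(map, surviving, profile,
                                      pixelSize = 0.145, binWidth = 0.005) {
  stopifnot(is(map, "CorrelationMap"), is(profile, "CurvatureProfile"))
  if (!any(map@edgeMask)) stop("empty edge mask")
  sel <- which(surviving & map@edgeMask & map@values > 0, arr.ind = TRUE)
  if (!nrow(sel)) stop("no surviving edge-band pixels")
  pts <- (sel - 1) * pixelSize
  coords <- profileCoordinates(profile)
  kap <- abs(profile@kappa[nearestContourIndex(coords, pts)])
  breaks <- seq(floor(min(kap) / binWidth) * binWidth,
                ceiling(max(kap) / binWidth + 1e-9) * binWidth,
                by = binWidth)
  if (length(breaks) < 2L) breaks <- c(breaks, breaks + binWidth)
  h <- hist(kap, breaks = breaks, plot = FALSE)
  freq <- 100 * h$counts / length(kap)
  fit <- fitGaussianCurve(h$mids, freq)
  list(mids = h$mids, frequency = freq, fit = fit)
}
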