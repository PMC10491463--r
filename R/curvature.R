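#' Spline curvature profile of a nuclear contour
#'
#' Interpolates the closed contour with a periodic cubic spline
#' (chord-length parameterization) and evaluates the planar curvature
#'
#' \deqn{\kappa = \frac{\dot x \ddot y - \dot y \ddot x}
#'                     {(\dot x^2 + \dot y^2)^{3/2}}}
#'
#' at \code{nSamples} points equally spaced in arc length. The expression is
#' invariant to the spline parameterization, so derivatives are taken with
#' respect to the chord parameter directly. For a counterclockwise contour
#' the sign is positive where the boundary bulges outward.
#'
#' @param contour a [NuclearContour-class].
#' @param nSamples number of equal-arc-length samples (default 400).
#' @param kappaFloor curvature floor (1/um) below which the radius of
#'   curvature is capped at \code{1/kappaFloor} (default 0.005, i.e. a
#'   200 um cap).
#' @return a [CurvatureProfile-class].
#' @examples
#' prof <- splineCurvature(ellipseContour(10, 10), nSamples = 100)
#' range(curvature(prof)$kappa)  # 0.1 1/um everywhere
#' @export
splineCurvature <- function(contour, nSamples = 400L, kappaFloor = 0.005) {
  stopifnot(is(contour, "NuclearContour"))
  x <- contour@x; y <- contour@y
  xc <- c(x, x[1]); yc <- c(y, y[1])
  u <- c(0, cumsum(sqrt(diff(xc)^2 + diff(yc)^2)))
  if (any(diff(u) == 0)) stop("contour has duplicate consecutive vertices")
  fx <- splinefun(u, xc, method = "periodic")
  fy <- splinefun(u, yc, method = "periodic")
  # arc length along the spline on a fine grid, then invert for equal-arc
  # sampling
  uf <- seq(0, max(u), length.out = max(20L * length(x), 2000L))
  speed <- sqrt(fx(uf, deriv = 1)^2 + fy(uf, deriv = 1)^2)
  arc <- c(0, cumsum((speed[-1] + speed[-length(speed)]) / 2 * diff(uf)))
  sOut <- seq(0, arc[length(arc)], length.out = nSamples + 1L)[-(nSamples + 1L)]
  uu <- approx(arc, uf, xout = sOut, ties = "ordered")$y
  xp <- fx(uu, deriv = 1); yp <- fy(uu, deriv = 1)
  xpp <- fx(uu, deriv = 2); ypp <- fy(uu, deriv = 2)
  kap <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  if (any(!is.finite(kap))) stop("curvature not finite; degenerate contour")
  rEq <- 1 / pmax(abs(kap), kappaFloor)
  new("CurvatureProfile", s = sOut, kappa = kap, rEq = rEq,
      kappaFloor = kappaFloor, contour = contour)
}

#' Contour coordinates at the curvature samples
#'
#' @param profile a [CurvatureProfile-class].
#' @return two-column matrix of (x, y) at the profile's arc-length samples.
#' @export
profileCoordinates <- function(profile) {
  stopifnot(is(profile, "CurvatureProfile"))
  ct <- profile@contour
  xc <- c(ct@x, ct@x[1]); yc <- c(ct@y, ct@y[1])
  u <- c(0, cumsum(sqrt(diff(xc)^2 + diff(yc)^2)))
  fx <- splinefun(u, xc, method = "periodic")
  fy <- splinefun(u, yc, method = "periodic")
  uf <- seq(0, max(u), length.out = max(20L * length(ct@x), 2000L))
  speed <- sqrt(fx(uf, deriv = 1)^2 + fy(uf, deriv = 1)^2)
  arc <- c(0, cumsum((speed[-1] + speed[-length(speed)]) / 2 * diff(uf)))
  uu <- approx(arc, uf, xout = profile@s, ties = "ordered")$y
  cbind(x = fx(uu), y = fy(uu))
}

#' Pooled curvature histogram with Gaussian fit
#'
#' Pools curvature magnitudes per cell, averages the per-cell frequency
#' distributions on a common grid, and fits a Gaussian by nonlinear least
#' squares. The frequency scale is percent of samples per bin.
#'
#' @param profiles a [CurvatureProfile-class] or list of them (one per cell).
#' @param binWidth histogram bin width in 1/um (default 0.025).
#' @param useAbs take curvature magnitudes (default TRUE; distributions are
#'   reported over positive curvatures).
#' @return list with \code{mids}, \code{frequency} (percent, averaged across
#'   cells) and \code{fit}, a [GaussianFit-class].
#' @export
curvatureHistogram <- function(profiles, binWidth = 0.025, useAbs = TRUE) {
  if (is(profiles, "CurvatureProfile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one curvature profile")
  vals <- lapply(profiles, function(p)
    if (useAbs) abs(p@kappa) else p@kappa)
  rng <- range(unlist(vals))
  breaks <- seq(floor(rng[1] / binWidth) * binWidth,
                ceiling(rng[2] / binWidth + 1e-9) * binWidth, by = binWidth)
  if (length(breaks) < 2L) breaks <- c(breaks, breaks + binWidth)
  freq <- vapply(vals, function(v) {
    h <- hist(v, breaks = breaks, plot = FALSE)
    100 * h$counts / length(v)
  }, numeric(length(breaks) - 1L))
  freq <- if (is.matrix(freq)) rowMeans(freq) else freq
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (sum(freq > 0) < 4L)
    stop("fewer than 4 nonempty bins; decrease binWidth")
  fit <- fitGaussianCurve(mids, freq)
  list(mids = mids, frequency = freq, fit = fit)
}

#' Nonlinear least-squares Gaussian fit to (x, y) data
#'
#' Fits \eqn{y = A \exp(-(x - \mu)^2 / (2\sigma^2))} with moment-based
#' starting values. Inputs without usable spread (e.g. a single spike, or a
#' flat response) are flagged degenerate rather than fitted.
#'
#' @param x,y numeric vectors (e.g. histogram bin centres and frequencies).
#' @return a [GaussianFit-class].
#' @export
fitGaussianCurve <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  degenerate <- function() new("GaussianFit", amplitude = NA_real_,
    mean = NA_real_, sigma = NA_real_, fwhm = NA_real_, r2 = NA_real_,
    degenerate = TRUE)
  if (length(x) < 4L || all(y <= 0) || sd(y) == 0) return(degenerate())
  w <- pmax(y, 0)
  mu0 <- sum(w * x) / sum(w)
  s0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) return(degenerate())
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(A = a0, mu = mu0, s = s0),
                      lower = c(0, -Inf, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(degenerate())
  cf <- coef(fit)
  r2 <- 1 - sum(resid(fit)^2) / sum((y - mean(y))^2)
  # flat or spike-like input: the Gaussian explains nothing
  if (!is.finite(r2) || r2 < 0.2) return(degenerate())
  new("GaussianFit", amplitude = unname(cf["A"]), mean = unname(cf["mu"]),
      sigma = unname(cf["s"]), fwhm = 2 * sqrt(2 * log(2)) * unname(cf["s"]),
      r2 = r2, degenerate = FALSE)
}
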