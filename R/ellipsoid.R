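#' Fit an ellipsoid nuclear model from a z-stack
#'
#' Estimates the nuclear semiaxes from the orthogonal projections of a
#' 3D stack: \code{a} and \code{b} from the thresholded xy
#' maximum-intensity projection via second-order moments of the mask
#' (for a filled ellipse the variance along a principal axis is
#' semiaxis^2/4), and \code{c} from the thresholded xz projection in the
#' same way. Sheppard's correction (voxel^2/12) removes the discretization
#' bias of the pixel-centre moments.
#'
#' @param stack 3D numeric array indexed \code{[x, y, z]}.
#' @param voxelSize length-3 numeric, voxel pitch (dx, dy, dz) in
#'   micrometres. Required; there is no safe isotropy assumption for
#'   confocal stacks.
#' @return an [EllipsoidModel-class] with semiaxes sorted so a >= b.
#' @export
fitEllipsoid <- function(stack, voxelSize) {
  if (missing(voxelSize) || length(voxelSize) != 3L || any(voxelSize <= 0))
    stop("voxelSize (dx, dy, dz) in um is required")
  if (length(dim(stack)) != 3L) stop("stack must be a 3D array")
  mipXY <- apply(stack, c(1, 2), max)
  mipXZ <- apply(stack, c(1, 3), max)
  maskXY <- .otsuMask(mipXY)
  maskXZ <- .otsuMask(mipXZ)
  if (!any(maskXY) || !any(maskXZ)) stop("no nucleus found in stack")
  ab <- .maskEllipseAxes(maskXY, voxelSize[1], voxelSize[2])
  cz <- .maskAxisExtent(maskXZ, axis = 2L, pitch = voxelSize[3])
  new("EllipsoidModel", a = max(ab), b = min(ab), c = cz)
}

.otsuMask <- function(plane) {
  rng <- range(plane)
  if (diff(rng) == 0) return(plane > rng[1])  # all-FALSE for constant planes
  norm <- (plane - rng[1]) / diff(rng)
  norm > EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
}

# Principal semiaxes of a filled 2D mask via second moments with Sheppard's
# discretization correction.
.maskEllipseAxes <- function(mask, dx, dy) {
  idx <- which(mask, arr.ind = TRUE)
  px <- (idx[, 1] - 1) * dx
  py <- (idx[, 2] - 1) * dy
  n <- nrow(idx)
  cv <- cov(cbind(px, py)) * (n - 1) / n
  cv[1, 1] <- max(cv[1, 1] - dx^2 / 12, 0)
  cv[2, 2] <- max(cv[2, 2] - dy^2 / 12, 0)
  ev <- eigen(cv, symmetric = TRUE)$values
  2 * sqrt(pmax(ev, 0))
}

# Semiaxis along one axis of a filled projection mask (variance-based, with
# Sheppard's correction), for the axial semiaxis c.
.maskAxisExtent <- function(mask, axis, pitch) {
  idx <- which(mask, arr.ind = TRUE)
  z <- (idx[, axis] - 1) * pitch
  n <- length(z)
  v <- var(z) * (n - 1) / n - pitch^2 / 12
  2 * sqrt(max(v, 0))
}

#' Meridian/parallel curvature decomposition on an ellipsoid
#'
#' Normal-section curvatures of the nuclear ellipsoid at an equatorial point
#' of parametric azimuth theta: \code{Keq} is the planar curvature of the
#' equatorial (a, b) ellipse, \code{Km} the curvature of the meridian
#' section (an ellipse with semiaxes r(theta), c, evaluated at its equator,
#' i.e. r(theta)/c^2 where r is the centre-to-point equatorial radius), and
#' the combined surface curvature \code{K = sqrt(Keq * Km)}, the square root
#' of the Gaussian curvature at the axis endpoints.
#'
#' @param model an [EllipsoidModel-class].
#' @param theta parametric azimuth(s) in radians; 0 is the tip of the major
#'   semiaxis a (point A), pi/2 the tip of b (point B).
#' @return data.frame with columns theta, Km, Keq, K (1/um).
#' @examples
#' ellipsoidCurvatures(new("EllipsoidModel", a = 5, b = 5, c = 5), 0)
#' @export
ellipsoidCurvatures <- function(model, theta = seq(0, 2 * pi, length.out = 181L)) {
  stopifnot(is(model, "EllipsoidModel"))
  a <- model@a; b <- model@b; cc <- model@c
  r <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  Keq <- a * b / (a^2 * sin(theta)^2 + b^2 * cos(theta)^2)^1.5
  Km <- r / cc^2
  data.frame(theta = theta, Km = Km, Keq = Keq, K = sqrt(Keq * Km))
}

#' Curvature variation factors between the equatorial axis tips
#'
#' Ratio of each curvature component between point A (tip of the major
#' semiaxis a) and point B (tip of the minor semiaxis b) on the equator:
#' \code{factorM = Km(A)/Km(B) = a/b} and
#' \code{factorEq = Keq(A)/Keq(B) = (a/b)^3}, so factorEq = factorM^3
#' identically. Elongated nuclei (a/b of 1.3 vs 1.8) therefore concentrate
#' most of their curvature variation in the equatorial component.
#'
#' @param model an [EllipsoidModel-class].
#' @return named numeric vector c(factorM, factorEq).
#' @export
curvatureVariationFactors <- function(model) {
  stopifnot(is(model, "EllipsoidModel"))
  ratio <- model@a / model@b
  c(factorM = ratio, factorEq = ratio^3)
}
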