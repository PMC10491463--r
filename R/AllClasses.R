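#' @import methods
#' @importFrom stats sd var median mad coef lm wilcox.test kruskal.test
#'   pt setNames splinefun approx quantile rnorm runif rpois nls resid fitted
NULL

#' Closed planar nuclear contour
#'
#' An ordered, counterclockwise, closed polygon describing the nuclear
#' envelope at one imaging plane, in physical micrometres. The closing edge
#' (last point back to first) is implicit: the first vertex is stored once.
#'
#' @slot x,y numeric vertex coordinates in micrometres.
#' @slot pixelSize numeric scalar, the source pixel size in micrometres
#'   (\code{NA} when the contour was supplied directly in physical units).
#'
#' @seealso [extractContour()], [splineCurvature()], [signedDistance()]
#' @export
setClass("NuclearContour",
  representation(x = "numeric", y = "numeric", pixelSize = "numeric"))

setValidity("NuclearContour", function(object) {
  msg <- NULL
  n <- length(object@x)
  if (n < 8L) msg <- c(msg, "contour needs at least 8 vertices")
  if (length(object@y) != n) msg <- c(msg, "x and y lengths differ")
  if (n >= 3L && anyNA(c(object@x, object@y)))
    msg <- c(msg, "contour coordinates must be finite")
  if (n >= 3L && !anyNA(c(object@x, object@y))) {
    if (.polygonArea(object@x, object@y) <= 0)
      msg <- c(msg, "contour must be counterclockwise with positive area")
  }
  if (is.null(msg)) TRUE else msg
})

#' Curvature profile along a nuclear contour
#'
#' Samples of the signed planar curvature kappa (1/um) at equally spaced
#' arc-length positions s along a [NuclearContour-class]. The radius of
#' curvature \code{rEq} is 1/|kappa|, capped where |kappa| falls below
#' \code{kappaFloor} to avoid division blow-ups.
#'
#' @slot s numeric arc-length positions (um).
#' @slot kappa numeric signed curvature (1/um); positive where the
#'   counterclockwise boundary bulges outward.
#' @slot rEq numeric radius of curvature (um).
#' @slot kappaFloor numeric scalar floor below which rEq is capped.
#' @slot contour the generating [NuclearContour-class].
#' @export
setClass("CurvatureProfile",
  representation(s = "numeric", kappa = "numeric", rEq = "numeric",
                 kappaFloor = "numeric", contour = "NuclearContour"))

setValidity("CurvatureProfile", function(object) {
  msg <- NULL
  if (length(object@s) != length(object@kappa))
    msg <- c(msg, "s and kappa lengths differ")
  if (any(!is.finite(object@kappa))) msg <- c(msg, "kappa must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Ellipsoidal nuclear shape model
#'
#' Semiaxes of the ellipsoid used to model the nucleus: \code{a >= b} are
#' the equatorial (xy-plane) semiaxes and \code{c} the axial (z) semiaxis,
#' all in micrometres.
#'
#' @slot a,b,c numeric semiaxis lengths (um), a >= b > 0, c > 0.
#' @seealso [fitEllipsoid()], [ellipsoidCurvatures()]
#' @export
setClass("EllipsoidModel",
  representation(a = "numeric", b = "numeric", c = "numeric"))

setValidity("EllipsoidModel", function(object) {
  msg <- NULL
  if (!(length(object@a) == 1L && length(object@b) == 1L &&
        length(object@c) == 1L))
    msg <- c(msg, "semiaxes must be scalars")
  else {
    if (!(object@b > 0 && object@c > 0)) msg <- c(msg, "semiaxes must be > 0")
    if (object@a < object@b) msg <- c(msg, "requires a >= b")
  }
  if (is.null(msg)) TRUE else msg
})

#' Gaussian fit summary
#'
#' Result of a nonlinear least-squares Gaussian fit to a frequency
#' distribution: amplitude, centre, width (sigma and the derived
#' FWHM = 2*sqrt(2*log(2))*sigma) and the coefficient of determination.
#' \code{degenerate} flags inputs too narrow or too flat to support a fit.
#'
#' @slot amplitude,mean,sigma,fwhm,r2 numeric scalars.
#' @slot degenerate logical flag.
#' @export
setClass("GaussianFit",
  representation(amplitude = "numeric", mean = "numeric", sigma = "numeric",
                 fwhm = "numeric", r2 = "numeric", degenerate = "logical"))

setValidity("GaussianFit", function(object) {
  if (!object@degenerate && length(object@sigma) == 1 &&
      is.finite(object@sigma) && object@sigma <= 0)
    "sigma must be positive" else TRUE
})

#' Normalized line-ROI intensity profile
#'
#' Fluorescence intensity along a line ROI with the position normalized to
#' [0, 1] (edge to opposite edge along the nuclear major axis) and the
#' intensity normalized to its maximum, so max(intensity) == 1.
#'
#' @slot position numeric, strictly increasing in [0, 1].
#' @slot intensity numeric, normalized so the maximum equals 1.
#' @export
setClass("IntensityProfile",
  representation(position = "numeric", intensity = "numeric"))

setValidity("IntensityProfile", function(object) {
  msg <- NULL
  if (length(object@position) != length(object@intensity))
    msg <- c(msg, "position and intensity lengths differ")
  if (is.unsorted(object@position, strictly = TRUE))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@intensity) &&
      abs(max(object@intensity) - 1) > 1e-8)
    msg <- c(msg, "intensity must be normalized to max 1")
  if (is.null(msg)) TRUE else msg
})

#' Two-segment linear fit of a lamin rim profile
#'
#' Piecewise-linear description of an edge-to-centre intensity profile: a
#' declining edge segment with slope \code{edgeSlope} up to the breakpoint,
#' then a second (interior) line. The lamina occupancy is 100 times the
#' breakpoint position.
#'
#' @slot edgeSlope numeric slope of the edge segment (per unit normalized
#'   position).
#' @slot breakpoint numeric breakpoint position in (0, 1).
#' @slot occupancy numeric, 100 * breakpoint (percent of the profile).
#' @slot innerSlope numeric slope of the interior segment.
#' @slot r2Edge,r2Inner numeric per-segment coefficients of determination.
#' @slot degenerate logical, TRUE when no breakpoint improves on a single
#'   line by more than 1\% of its residual sum of squares.
#' @export
setClass("TwoSegmentFit",
  representation(edgeSlope = "numeric", breakpoint = "numeric",
                 occupancy = "numeric", innerSlope = "numeric",
                 r2Edge = "numeric", r2Inner = "numeric",
                 degenerate = "logical"))

setValidity("TwoSegmentFit", function(object) {
  if (!object@degenerate &&
      !(object@breakpoint > 0 && object@breakpoint < 1))
    "breakpoint must lie in (0, 1)" else TRUE
})

#' Fiber directionality histogram
#'
#' Orientation histogram of local image structure from -90 to +90 degrees in
#' 1-degree bins (181 bins), weights normalized to sum to 1.
#'
#' @slot angle numeric bin centres in degrees, -90..90 step 1.
#' @slot weight numeric nonnegative weights summing to 1.
#' @slot peakAngle numeric angle of the maximal bin.
#' @export
setClass("DirectionalityHistogram",
  representation(angle = "numeric", weight = "numeric", peakAngle = "numeric"))

setValidity("DirectionalityHistogram", function(object) {
  msg <- NULL
  if (length(object@angle) != 181L || length(object@weight) != 181L)
    msg <- c(msg, "histogram must have 181 bins (-90..90 step 1)")
  if (any(object@weight < 0)) msg <- c(msg, "weights must be nonnegative")
  if (abs(sum(object@weight) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  if (is.null(msg)) TRUE else msg
})

#' Local correlation map between two channels
#'
#' Per-pixel Pearson correlation of two registered images over a sliding
#' window, together with disjoint edge-band and interior region masks and a
#' mask of pixels where the correlation was undefined (constant window).
#'
#' @slot values numeric matrix of correlations in [-1, 1].
#' @slot edgeMask,interiorMask logical matrices, disjoint regions.
#' @slot undefinedMask logical matrix, TRUE where correlation was undefined.
#' @export
setClass("CorrelationMap",
  representation(values = "matrix", edgeMask = "matrix",
                 interiorMask = "matrix", undefinedMask = "matrix"))

setValidity("CorrelationMap", function(object) {
  msg <- NULL
  v <- object@values[!object@undefinedMask]
  if (length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
    msg <- c(msg, "correlation values must lie in [-1, 1]")
  if (any(object@edgeMask & object@interiorMask))
    msg <- c(msg, "edge and interior masks must be disjoint")
  if (is.null(msg)) TRUE else msg
})

#' Constant-stress creep curve
#'
#' Strain versus time under a constant applied force, as produced by a
#' constant-force pulling experiment or simulation. Time units are carried
#' explicitly ("s" or "ns") so the fitted viscosity is reported in GPa.s or
#' GPa.ns accordingly. The applied force (pN) and the cross-sectional area
#' (Angstrom^2) determine the instantaneous stress sigma0 = F/A.
#'
#' @slot time numeric, strictly increasing.
#' @slot strain numeric engineering strain (dimensionless).
#' @slot timeUnit character, "s" or "ns".
#' @slot force numeric applied force in pN.
#' @slot area numeric cross-sectional area in Angstrom^2.
#' @export
setClass("CreepCurve",
  representation(time = "numeric", strain = "numeric", timeUnit = "character",
                 force = "numeric", area = "numeric"))

setValidity("CreepCurve", function(object) {
  msg <- NULL
  if (length(object@time) != length(object@strain))
    msg <- c(msg, "time and strain lengths differ")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "time must be strictly increasing")
  if (!object@timeUnit %in% c("s", "ns"))
    msg <- c(msg, "timeUnit must be 's' or 'ns'")
  if (object@force < 0) msg <- c(msg, "force must be >= 0")
  if (object@area <= 0) msg <- c(msg, "area must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Kelvin-Voigt fit parameters
#'
#' Parameters of the Kelvin-Voigt viscoelastic solid fitted to a creep
#' curve: spring modulus E (GPa) in parallel with a dashpot of viscosity
#' eta (GPa.s, or GPa.ns when the curve's time axis is ns), with the applied
#' instantaneous stress sigma0 (GPa).
#'
#' @slot E,eta,sigma0,r2 numeric scalars.
#' @slot cov numeric 2x2 covariance matrix of (E, eta).
#' @slot timeUnit character, "s" or "ns".
#' @slot plateauReached logical, FALSE when the curve spans fewer than two
#'   retardation times so the plateau is extrapolated.
#' @export
setClass("KelvinVoigtParams",
  representation(E = "numeric", eta = "numeric", sigma0 = "numeric",
                 cov = "matrix", r2 = "numeric", timeUnit = "character",
                 plateauReached = "logical"))

setValidity("KelvinVoigtParams", function(object) {
  if (object@E <= 0 || object@eta <= 0)
    "E and eta must be positive" else TRUE
})

.polygonArea <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}
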