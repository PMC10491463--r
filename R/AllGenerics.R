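#' Accessors for nucleomech S4 classes
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{contourPoints} returns the vertex matrix of a contour,
#' \code{semiaxes} the (a, b, c) of an ellipsoid model, \code{curvature}
#' the kappa samples of a curvature profile, \code{radiusOfCurvature} the
#' capped 1/kappa samples, \code{occupancy} the lamina occupancy percent of
#' a two-segment fit, and \code{edgeSlope} its edge-segment slope.
#'
#' @param object an object of the documented class.
#' @return See each method's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contourPoints", function(object) standardGeneric("contourPoints"))
#' @rdname accessors
#' @export
setGeneric("semiaxes", function(object) standardGeneric("semiaxes"))
#' @rdname accessors
#' @export
setGeneric("curvature", function(object) standardGeneric("curvature"))
#' @rdname accessors
#' @export
setGeneric("radiusOfCurvature",
           function(object) standardGeneric("radiusOfCurvature"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("edgeSlope", function(object) standardGeneric("edgeSlope"))

#' @rdname accessors
#' @export
setMethod("contourPoints", "NuclearContour", function(object)
  cbind(x = object@x, y = object@y))

#' @rdname accessors
#' @export
setMethod("semiaxes", "EllipsoidModel", function(object)
  c(a = object@a, b = object@b, c = object@c))

#' @rdname accessors
#' @export
setMethod("curvature", "CurvatureProfile", function(object)
  data.frame(s = object@s, kappa = object@kappa))

#' @rdname accessors
#' @export
setMethod("radiusOfCurvature", "CurvatureProfile", function(object)
  object@rEq)

#' @rdname accessors
#' @export
setMethod("occupancy", "TwoSegmentFit", function(object) object@occupancy)

#' @rdname accessors
#' @export
setMethod("edgeSlope", "TwoSegmentFit", function(object) object@edgeSlope)

setMethod("show", "NuclearContour", function(object) {
  cat(sprintf("NuclearContour: %d vertices, area %.2f um^2, perimeter %.2f um\n",
              length(object@x), .polygonArea(object@x, object@y),
              .polygonPerimeter(object@x, object@y)))
})

setMethod("show", "CurvatureProfile", function(object) {
  cat(sprintf(
    "CurvatureProfile: %d samples, kappa in [%.4f, %.4f] 1/um (floor %.3g)\n",
    length(object@kappa), min(object@kappa), max(object@kappa),
    object@kappaFloor))
})

setMethod("show", "EllipsoidModel", function(object) {
  cat(sprintf("EllipsoidModel: a=%.3f, b=%.3f, c=%.3f um (b/c = %.2f)\n",
              object@a, object@b, object@c, object@b / object@c))
})

setMethod("show", "GaussianFit", function(object) {
  if (object@degenerate) {
    cat("GaussianFit: degenerate (no usable Gaussian structure)\n")
  } else {
    cat(sprintf(
      "GaussianFit: amplitude=%.4g, mean=%.4g, sigma=%.4g, FWHM=%.4g, R2=%.3f\n",
      object@amplitude, object@mean, object@sigma, object@fwhm, object@r2))
  }
})

setMethod("show", "TwoSegmentFit", function(object) {
  if (object@degenerate) {
    cat(sprintf("TwoSegmentFit: degenerate, whole-profile slope %.4f\n",
                object@edgeSlope))
  } else {
    cat(sprintf(
      "TwoSegmentFit: edge slope %.4f, breakpoint %.3f (occupancy %.1f%%)\n",
      object@edgeSlope, object@breakpoint, object@occupancy))
  }
})

setMethod("show", "DirectionalityHistogram", function(object) {
  cat(sprintf("DirectionalityHistogram: 181 bins, peak at %d deg\n",
              as.integer(object@peakAngle)))
})

setMethod("show", "CorrelationMap", function(object) {
  cat(sprintf("CorrelationMap: %d x %d, %d edge px, %d interior px\n",
              nrow(object@values), ncol(object@values),
              sum(object@edgeMask), sum(object@interiorMask)))
})

setMethod("show", "CreepCurve", function(object) {
  cat(sprintf(
    "CreepCurve: %d samples over %.3g %s, F=%.3g pN, A=%.4g A^2 (sigma0=%.4g GPa)\n",
    length(object@time), max(object@time), object@timeUnit, object@force,
    object@area, stressFromForce(object@force, object@area)))
})

setMethod("show", "KelvinVoigtParams", function(object) {
  cat(sprintf(
    "KelvinVoigtParams: E=%.4g GPa, eta=%.4g GPa.%s, sigma0=%.4g GPa, R2=%.4f\n",
    object@E, object@eta, object@timeUnit, object@sigma0, object@r2))
})

.polygonPerimeter <- function(x, y) {
  n <- length(x)
  j <- c(seq(2, n), 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}
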