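#' Construct a nuclear contour from vertex coordinates
#'
#' Builds a [NuclearContour-class] from ordered polygon vertices in
#' micrometres. A duplicated closing vertex is dropped, the orientation is
#' normalized to counterclockwise, and the polygon is checked for
#' self-intersection.
#'
#' @param x,y numeric vertex coordinates in micrometres, ordered along the
#'   boundary.
#' @param pixelSize source pixel size in micrometres (NA if not applicable).
#' @param checkSimple logical, verify the polygon is simple
#'   (non-self-intersecting). Quadratic in the vertex count; disable for
#'   very dense contours known to be valid.
#' @return a [NuclearContour-class].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' nc <- nuclearContour(10 * cos(th), 10 * sin(th))
#' @export
nuclearContour <- function(x, y, pixelSize = NA_real_, checkSimple = TRUE) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 8L) stop("contour needs at least 8 vertices")
  keep <- c(TRUE, (diff(x) != 0 | diff(y) != 0))
  x <- x[keep]; y <- y[keep]
  if (.polygonArea(x, y) < 0) {
    x <- rev(x); y <- rev(y)
  }
  if (.polygonArea(x, y) == 0) stop("degenerate contour with zero area")
  if (checkSimple && .selfIntersects(x, y))
    stop("contour is self-intersecting")
  new("NuclearContour", x = x, y = y, pixelSize = pixelSize)
}

# Segment-pair intersection test (excluding shared endpoints of adjacent
# edges); O(n^2) but vectorized across the inner loop.
.selfIntersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j < n]  # edge n is adjacent to edge 1
    if (!length(j)) next
    d1 <- (x2[i] - x[i]) * (y[j] - y[i]) - (y2[i] - y[i]) * (x[j] - x[i])
    d2 <- (x2[i] - x[i]) * (y2[j] - y[i]) - (y2[i] - y[i]) * (x2[j] - x[i])
    d3 <- (x2[j] - x[j]) * (y[i] - y[j]) - (y2[j] - y[j]) * (x[i] - x[j])
    d4 <- (x2[j] - x[j]) * (y2[i] - y[j]) - (y2[j] - y[j]) * (x2[i] - x[j])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Extract the nuclear contour from an image plane
#'
#' Identifies the nuclear boundary at one imaging plane, mirroring the
#' manual-ROI workflow: if a polygon ROI is supplied it takes precedence;
#' otherwise the plane is lightly smoothed, thresholded by Otsu's method,
#' and the boundary of the largest connected region is traced.
#'
#' @param plane numeric matrix, one image plane indexed \code{[x, y]} with
#'   pixel centres at 0-based integer coordinates.
#' @param pixelSize pixel size in micrometres (default 0.145).
#' @param roi optional two-column matrix or data.frame of polygon vertices
#'   in micrometres (a manual ROI); used verbatim when supplied.
#' @param smoothSigma Gaussian smoothing sigma in pixels before Otsu
#'   thresholding.
#' @param minAreaFrac regions with area above this fraction of the largest
#'   region count as competing candidates and raise an error.
#' @param smoothWindow circular moving-average window (in boundary
#'   vertices) applied to the traced boundary, and subsampling step: the
#'   raw trace is pixel-stepped, and an unsmoothed staircase polygon would
#'   dominate any downstream spline curvature.
#' @param step keep every \code{step}-th smoothed boundary vertex.
#' @return a [NuclearContour-class] in micrometres.
#' @export
extractContour <- function(plane, pixelSize = 0.145, roi = NULL,
                           smoothSigma = 1, minAreaFrac = 0.5,
                           smoothWindow = 9L, step = 4L) {
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    return(nuclearContour(roi[, 1], roi[, 2], pixelSize = pixelSize))
  }
  img <- EBImage::Image(plane)
  if (smoothSigma > 0) img <- EBImage::gblur(img, sigma = smoothSigma)
  rng <- range(EBImage::imageData(img))
  if (diff(rng) == 0) stop("no foreground region: image is constant")
  norm <- (EBImage::imageData(img) - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  if (!any(mask)) stop("no foreground region after thresholding")
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  areas <- tabulate(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  biggest <- which.max(areas)
  rivals <- which(areas >= minAreaFrac * areas[biggest])
  if (length(rivals) > 1L)
    stop(sprintf(
      "multiple similar-size regions (labels %s); provide a manual ROI",
      paste(rivals, collapse = ", ")))
  oc <- EBImage::ocontour(EBImage::Image(
    EBImage::imageData(lab) == biggest))[[1]]
  if (nrow(oc) < 8L) stop("traced boundary too short")
  x <- oc[, 1]; y <- oc[, 2]
  if (smoothWindow > 1L && nrow(oc) > 3L * smoothWindow) {
    x <- .circularSmooth(x, smoothWindow)
    y <- .circularSmooth(y, smoothWindow)
  }
  if (step > 1L && length(x) >= 8L * step) {
    keep <- seq(1L, length(x), by = step)
    x <- x[keep]; y <- y[keep]
  }
  nuclearContour(x * pixelSize, y * pixelSize,
                 pixelSize = pixelSize, checkSimple = FALSE)
}

#' Signed distance from points to a nuclear contour
#'
#' Euclidean distance from each query point to the nearest point on the
#' closed polygonal contour, negative inside the nucleus and positive
#' outside.
#'
#' @param contour a [NuclearContour-class].
#' @param points two-column matrix (x, y) in micrometres, or a length-2
#'   vector for a single point.
#' @return numeric vector of signed distances in micrometres.
#' @export
signedDistance <- function(contour, points) {
  stopifnot(is(contour, "NuclearContour"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  px <- points[, 1]; py <- points[, 2]
  vx <- contour@x; vy <- contour@y
  wx <- c(vx[-1], vx[1]); wy <- c(vy[-1], vy[1])
  ex <- wx - vx; ey <- wy - vy
  len2 <- ex^2 + ey^2
  d2 <- rep(Inf, length(px))
  for (i in seq_along(vx)) {
    t <- ((px - vx[i]) * ex[i] + (py - vy[i]) * ey[i]) / len2[i]
    t <- pmin(1, pmax(0, t))
    dx <- px - (vx[i] + t * ex[i]); dy <- py - (vy[i] + t * ey[i])
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2) * ifelse(.pointInPolygon(px, py, vx, vy), -1, 1)
}

# Even-odd rule point-in-polygon, vectorized over points.
.pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Nearest contour sample index for query points
#'
#' Index (into the contour's vertex list, or into the supplied sample
#' coordinates) of the contour point nearest each query point. Used to
#' attach local curvature to tracking events and edge pixels.
#'
#' @param contour a [NuclearContour-class] or a two-column coordinate matrix.
#' @param points two-column matrix (x, y).
#' @return integer vector of nearest indices.
#' @export
nearestContourIndex <- function(contour, points) {
  if (is(contour, "NuclearContour")) {
    cx <- contour@x; cy <- contour@y
  } else {
    cx <- contour[, 1]; cy <- contour[, 2]
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  idx <- integer(nrow(points))
  # chunk over points to bound the distance-matrix size
  step <- max(1L, floor(4e6 / length(cx)))
  for (s in seq(1, nrow(points), by = step)) {
    e <- min(nrow(points), s + step - 1L)
    dx <- outer(points[s:e, 1], cx, "-")
    dy <- outer(points[s:e, 2], cy, "-")
    idx[s:e] <- max.col(-(dx^2 + dy^2), ties.method = "first")
  }
  idx
}

# Circular moving average over a closed vertex sequence.
.circularSmooth <- function(v, w) {
  h <- (w - 1L) %/% 2L
  n <- length(v)
  ext <- c(v[(n - h + 1L):n], v, v[1:h])
  as.numeric(stats::filter(ext, rep(1 / (2 * h + 1), 2 * h + 1)))[
    (h + 1L):(h + n)]
}

# Exact projection of points onto the polygon boundary (nearest point on
# any edge). Used by the generators so that molecules stopped at the
# envelope have signed distance exactly zero.
.projectToPolygon <- function(contour, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  px <- points[, 1]; py <- points[, 2]
  vx <- contour@x; vy <- contour@y
  wx <- c(vx[-1], vx[1]); wy <- c(vy[-1], vy[1])
  ex <- wx - vx; ey <- wy - vy
  len2 <- ex^2 + ey^2
  best <- rep(Inf, length(px))
  bx <- px; by <- py
  for (i in seq_along(vx)) {
    t <- ((px - vx[i]) * ex[i] + (py - vy[i]) * ey[i]) / len2[i]
    t <- pmin(1, pmax(0, t))
    qx <- vx[i] + t * ex[i]; qy <- vy[i] + t * ey[i]
    d2 <- (px - qx)^2 + (py - qy)^2
    upd <- d2 < best
    best[upd] <- d2[upd]; bx[upd] <- qx[upd]; by[upd] <- qy[upd]
  }
  cbind(bx, by)
}

#' Circular or elliptical reference contours
#'
#' Convenience constructors for analytic boundaries, used throughout the
#' synthetic generators and tests.
#'
#' @param a,b semiaxes in micrometres (equal for a circle).
#' @param n number of vertices.
#' @param center length-2 centre (um).
#' @return a [NuclearContour-class].
#' @export
ellipseContour <- function(a, b = a, n = 256L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  nuclearContour(center[1] + a * cos(th), center[2] + b * sin(th),
                 checkSimple = FALSE)
}
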