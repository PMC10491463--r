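# Shared oracles and constructions, independent of the implementation paths
# they check.

# Equal-arc-length vertices of an analytic closed curve given parametric
# functions fx(t), fy(t) on [0, 2*pi).
equalArcVertices <- function(fx, fy, n, nFine = 20000L) {
  tt <- seq(0, 2 * pi, length.out = nFine + 1L)
  x <- fx(tt); y <- fy(tt)
  arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  sTar <- seq(0, arc[nFine + 1L], length.out = n + 1L)[-(n + 1L)]
  ti <- approx(arc, tt, xout = sTar, ties = "ordered")$y
  cbind(x = fx(ti), y = fy(ti))
}

# Centered finite-difference curvature at the vertices of a closed polygon,
# treating the vertex index as the parameter (valid for equal-arc spacing).
fdCurvature <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))
  xp <- (x[ip] - x[im]) / 2
  yp <- (y[ip] - y[im]) / 2
  xpp <- x[ip] - 2 * x + x[im]
  ypp <- y[ip] - 2 * y + y[im]
  (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
}

# Brute-force optimal 2-vs-2 frame assignment minimizing total distance,
# with links above rMax forbidden. Returns the index of the next-frame spot
# matched to each current spot (NA when unmatched).
bruteMatch2 <- function(cur, nxt, rMax = 1.0) {
  d <- sqrt(outer(cur[, 1], nxt[, 1], "-")^2 +
            outer(cur[, 2], nxt[, 2], "-")^2)
  best <- c(NA_integer_, NA_integer_); bestCost <- Inf; bestN <- 0L
  for (perm in list(c(1L, 2L), c(2L, 1L))) {
    ok <- d[cbind(1:2, perm)] <= rMax
    cost <- sum(d[cbind(1:2, perm)][ok])
    if (sum(ok) > bestN || (sum(ok) == bestN && cost < bestCost)) {
      bestN <- sum(ok); bestCost <- cost
      best <- ifelse(ok, perm, NA_integer_)
    }
  }
  best
}

# Surviving-pixel construction for colocalization-vs-curvature: pixels in
# the edge band of an elliptical contour selected by importance reweighting
# so their curvature magnitudes follow N(mu, sigma). Returns the map, the
# survival mask, the curvature profile, and the realized kappa sample.
colocConstruction <- function(mu = 0.057, sigma = 0.012, seed = 1L,
                              pixelSize = 0.145) {
  set.seed(seed)
  ct <- ellipseContour(10, 3, n = 512, center = c(12, 12))
  prof <- splineCurvature(ct, nSamples = 1600)
  n <- as.integer(ceiling(24 / pixelSize)) + 1L
  gx <- rep((0:(n - 1)) * pixelSize, times = n)
  gy <- rep((0:(n - 1)) * pixelSize, each = n)
  d <- signedDistance(ct, cbind(gx, gy))
  band <- d <= 0 & d >= -5 * pixelSize
  coords <- profileCoordinates(prof)
  ni <- nearestContourIndex(coords, cbind(gx[band], gy[band]))
  kap <- abs(prof@kappa[ni])
  dens <- density(kap, from = min(kap), to = max(kap), n = 512)
  di <- approx(dens$x, dens$y, kap)$y
  w <- dnorm(kap, mu, sigma) / pmax(di, quantile(di, 0.1))
  sel <- runif(length(w)) < w / max(w)
  surv <- matrix(FALSE, n, n); edge <- matrix(FALSE, n, n)
  bandIdx <- which(matrix(band, n, n), arr.ind = TRUE)
  edge[bandIdx] <- TRUE
  surv[bandIdx[sel, , drop = FALSE]] <- TRUE
  cmap <- new("CorrelationMap", values = matrix(0.9, n, n),
              edgeMask = edge, interiorMask = matrix(FALSE, n, n),
              undefinedMask = matrix(FALSE, n, n))
  list(map = cmap, surviving = surv, profile = prof,
       kappaSelected = kap[sel], pixelSize = pixelSize)
}

# Minimal synthetic two-chain PDB text (CA atoms of residues 79 and 222),
# standing in for a real coiled-coil structure file.
writeSyntheticPDB <- function(path, fixed, steered) {
  lines <- character(0)
  fmt <- function(serial, resno, chain, xyz)
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, chain, resno, xyz[1], xyz[2], xyz[3])
  serial <- 1L
  for (i in seq_len(nrow(fixed))) {
    ch <- LETTERS[i]
    lines <- c(lines, fmt(serial, 79L, ch, fixed[i, ]))
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, 222L, ch, steered[i, ]))
    serial <- serial + 1L
  }
  writeLines(c(lines, "END"), path)
  path
}
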