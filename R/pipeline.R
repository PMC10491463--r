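#' Default per-condition generator parameters
#'
#' The synthetic cohort emulates the three culture conditions with their
#' characteristic nuclear geometry and lamina organization: semiaxis ratios
#' b/c of 3 (Flat), 2 (Flat+CD) and 1 (Nichoid) with the axial semiaxis
#' doubling from Flat to Nichoid; equatorial elongation a/b of 1.3 (Flat)
#' and 1.8 (Nichoid); lamin edge slopes of -0.183 +/- 0.089 (Flat),
#' -0.386 +/- 0.214 (Flat+CD) and -0.765 +/- 0.356 (Nichoid); lamina
#' occupancy breakpoints of 0.64 (Flat) and 0.21 (Nichoid), with the
#' treated condition in between; and an edge-band texture CV increasing
#' from Flat to Nichoid. Chromatin clustering decreases from Flat to
#' Nichoid (the treated condition resembles the Nichoid), so the line-ROI
#' CV ordering follows.
#'
#' @return named list of per-condition parameter lists.
#' @export
defaultCohortParams <- function() {
  list(
    "Flat" = list(
      semiaxes = c(a = 8.19, b = 6.30, c = 2.10),
      alphaMean = -0.183, alphaSd = 0.089,
      breakpoint = 0.64, breakpointSd = 0.03,
      interiorLevel = 0.88, edgeCv = 0.10, rimBoost = 0.15,
      clusterStrength = 1.5),
    "Flat+CD" = list(
      semiaxes = c(a = 7.50, b = 5.00, c = 2.50),
      alphaMean = -0.386, alphaSd = 0.214,
      breakpoint = 0.45, breakpointSd = 0.03,
      interiorLevel = 0.78, edgeCv = 0.18, rimBoost = 0.30,
      clusterStrength = 0.7),
    "Nichoid" = list(
      semiaxes = c(a = 7.02, b = 3.90, c = 3.90),
      alphaMean = -0.765, alphaSd = 0.356,
      breakpoint = 0.21, breakpointSd = 0.03,
      interiorLevel = 0.75, edgeCv = 0.30, rimBoost = 0.50,
      clusterStrength = 0.5))
}

#' Simulate a per-cell metric cohort
#'
#' Generates, per cell, a lamin equatorial plane and a chromatin plane with
#' condition-specific parameters (per-cell slope and breakpoint drawn
#' around the condition means), runs the morphometry estimators on the
#' images, and returns the long-format cohort table with metrics:
#' \code{alpha} (lamin edge slope), \code{occupancy} (lamina occupancy
#' percent), \code{beta} (edge/interior ratio), \code{edge_cv} (lamin
#' edge-band CV) and \code{chromatin_cv} (line-ROI CV of the chromatin
#' plane).
#'
#' @param conditions condition labels to simulate (must be names of
#'   \code{params}).
#' @param nCells cells per condition (default 50).
#' @param params per-condition parameters, see [defaultCohortParams()].
#' @param pixelSize pixel size in um.
#' @param radiusUm nuclear radius of the simulated planes (um).
#' @param readSd additive noise sd on the generated planes.
#' @param seed master seed; each cell gets a derived child seed.
#' @return a cohort table data.frame (cell_id, condition, metric, value).
#' @export
simulateCohort <- function(conditions = c("Flat", "Flat+CD", "Nichoid"),
                           nCells = 50L, params = defaultCohortParams(),
                           pixelSize = 0.145, radiusUm = 5, readSd = 0.01,
                           seed = 1L) {
  stopifnot(all(conditions %in% names(params)))
  rows <- vector("list", length(conditions) * nCells)
  k <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    pp <- params[[cond]]
    for (i in seq_len(nCells)) {
      childSeed <- (seed * 1009L + ci * 97L + i * 7919L) %% 2147483647L
      set.seed(childSeed)
      alpha <- min(rnorm(1, pp$alphaMean, pp$alphaSd), -0.02)
      bp <- min(max(rnorm(1, pp$breakpoint, pp$breakpointSd), 0.05), 0.9)
      # profile plane: smooth rim signal for the slope/occupancy fit; the
      # edge texture is a property of the rim plane measured below
      lam <- makeLaminPlanes(radiusUm = radiusUm, breakpointFrac = bp,
                             edgeSlope = alpha,
                             interiorLevel = pp$interiorLevel,
                             edgeCv = 0, pixelSize = pixelSize,
                             readSd = readSd, seed = childSeed)
      prof <- majorAxisProfile(lam$lamin, lam$contour, pixelSize = pixelSize)
      fit <- twoSegmentFit(prof)
      # beta and edge CV come from a plane with the radial lamina rim
      rim <- makeLaminPlanes(radiusUm = radiusUm, breakpointFrac = bp,
                             edgeSlope = alpha,
                             interiorLevel = pp$interiorLevel,
                             edgeCv = pp$edgeCv, rimBoost = pp$rimBoost,
                             pixelSize = pixelSize, readSd = readSd,
                             seed = childSeed + 2L)
      masks <- nuclearRegionMasks(rim$lamin, rim$contour,
                                  pixelSize = pixelSize)
      beta <- betaRatio(rim$lamin, rim$contour, pixelSize = pixelSize,
                        masks = masks)
      edgeCv <- coefficientOfVariation(rim$lamin[masks$edge])
      chr <- makeChromatinPlane(pp$clusterStrength, radiusUm = radiusUm,
                                pixelSize = pixelSize, readSd = readSd,
                                seed = childSeed + 1L)
      chrCv <- linearRoiCV(chr$plane, chr$contour,
                           inwardLengthUm = 0.7 * radiusUm,
                           pixelSize = pixelSize,
                           startAngle = runif(1, 0, 2 * pi))
      k <- k + 1L
      rows[[k]] <- data.frame(
        cell_id = sprintf("%s_%03d", gsub("[^A-Za-z]", "", cond), i),
        condition = cond,
        metric = c("alpha", "occupancy", "beta", "edge_cv", "chromatin_cv"),
        value = c(fit@edgeSlope,
                  if (fit@degenerate) NA_real_ else fit@occupancy,
                  beta, edgeCv, chrCv))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validateCohortTable(out)
  out
}

#' Run the full simulate-measure-compare pipeline
#'
#' Validates a configuration (a named list or a YAML file path), simulates
#' the cohort, compares every metric across conditions with the
#' appropriate non-parametric test, and (optionally) writes cohort and
#' comparison tables as CSV, a run summary as JSON, and per-metric boxplot
#' figures as PNG under the output directory. Reruns with the same
#' configuration are bit-identical for the tables.
#'
#' @param config named list or path to a YAML file with fields \code{seed}
#'   (integer), \code{nCells} (integer >= 3), \code{conditions} (>= 2
#'   labels from [conditionLevels()]); optional \code{pixelSize},
#'   \code{radiusUm}, \code{readSd}, \code{outDir}, \code{figures}.
#' @return list with \code{cohort}, \code{comparisons}, \code{runId} and
#'   \code{outDir} (NULL when nothing was written).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validateConfig(config)
  h <- .configHash(config)
  runId <- sprintf("run-%04x%04x-seed%d", h %/% 65536, h %% 65536,
                   config$seed)
  cohort <- simulateCohort(conditions = config$conditions,
                           nCells = config$nCells,
                           pixelSize = config$pixelSize,
                           radiusUm = config$radiusUm,
                           readSd = config$readSd, seed = config$seed)
  comparisons <- compareAllMetrics(
    cohort[!is.na(cohort$value), ], conditions = config$conditions)
  outDir <- NULL
  if (!is.null(config$outDir)) {
    outDir <- file.path(config$outDir, runId)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort, file.path(outDir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(outDir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(runId = runId, config = config,
           nRows = nrow(cohort),
           metrics = sort(unique(cohort$metric))),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
    if (isTRUE(config$figures)) {
      for (m in unique(cohort$metric)) {
        grDevices::png(file.path(outDir, paste0("boxplot_", m, ".png")),
                       width = 600, height = 450)
        sub <- cohort[cohort$metric == m & !is.na(cohort$value), ]
        graphics::boxplot(value ~ factor(condition,
                                         levels = config$conditions),
                          data = sub, main = m, xlab = "", ylab = m)
        grDevices::dev.off()
      }
    }
  }
  list(cohort = cohort, comparisons = comparisons, runId = runId,
       outDir = outDir)
}

.validateConfig <- function(config) {
  if (!is.list(config)) stop("config must be a list or YAML path")
  for (f in c("seed", "nCells", "conditions"))
    if (is.null(config[[f]])) stop("config is missing required field: ", f)
  config$seed <- as.integer(config$seed)
  config$nCells <- as.integer(config$nCells)
  if (is.na(config$seed)) stop("config seed must be an integer")
  if (is.na(config$nCells) || config$nCells < 3L)
    stop("config nCells must be an integer >= 3")
  bad <- setdiff(config$conditions, conditionLevels())
  if (length(bad))
    stop("unknown condition label(s) in config: ", paste(bad, collapse = ", "))
  if (length(config$conditions) < 2L) stop("config needs >= 2 conditions")
  if (is.null(config$pixelSize)) config$pixelSize <- 0.145
  if (is.null(config$radiusUm)) config$radiusUm <- 5
  if (is.null(config$readSd)) config$readSd <- 0.01
  if (is.null(config$figures)) config$figures <- FALSE
  config
}

# FNV-1a 32-bit hash of the serialized configuration, for run provenance.
.configHash <- function(config) {
  s <- paste(deparse(config[sort(names(config))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # exact 32-bit modular multiply in double precision
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  h
}
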