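#' Read and write multi-page TIFF stacks
#'
#' Images are held in memory as numeric matrices/arrays indexed
#' \code{[x, y(, page)]}; on disk the usual TIFF row-major layout is used,
#' so planes are transposed on the way in and out. Intensities are clipped
#' to [0, 1] on write (32-bit float samples).
#'
#' @param stack numeric matrix or 3D array (pages as the third dimension).
#' @param path file path.
#' @return \code{readImageTIFF} returns a matrix (single page) or array.
#' @export
writeImageTIFF <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3]), function(k)
    t(pmin(pmax(stack[, , k], 0), 1)))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readImageTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    t(p)
  })
  if (length(pages) == 1L) return(pages[[1]])
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Read and write track tables as CSV
#'
#' Track CSVs carry columns \code{track_id}, \code{frame} and either
#' \code{x_um}/\code{y_um} (micrometres) or \code{x_px}/\code{y_px}
#' (pixels, converted using \code{pixelSize}); the column names are the
#' unit flag.
#'
#' @param tracks data.frame with track_id, frame, x_um, y_um.
#' @param path file path.
#' @param pixelSize pixel size in um, used to convert pixel-unit tables.
#' @return \code{readTracksCSV} returns a data.frame with x_um/y_um.
#' @export
writeTracksCSV <- function(tracks, path) {
  utils::write.csv(tracks[, c("track_id", "frame", "x_um", "y_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeTracksCSV
#' @export
readTracksCSV <- function(path, pixelSize = 0.145) {
  df <- utils::read.csv(path)
  if (all(c("x_um", "y_um") %in% names(df))) {
    out <- df[, c("track_id", "frame", "x_um", "y_um")]
  } else if (all(c("x_px", "y_px") %in% names(df))) {
    out <- data.frame(track_id = df$track_id, frame = df$frame,
                      x_um = df$x_px * pixelSize,
                      y_um = df$y_px * pixelSize)
  } else {
    stop("track CSV needs x_um/y_um or x_px/y_px columns")
  }
  out[order(out$track_id, out$frame), ]
}

#' Read a polygon ROI from CSV
#'
#' @param path CSV with columns x_um, y_um (ordered polygon vertices).
#' @return two-column matrix in micrometres.
#' @export
readRoiCSV <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_um", "y_um") %in% names(df)))
  as.matrix(df[, c("x_um", "y_um")])
}

#' Write a fit result as JSON
#'
#' Serializes S4 fit objects ([GaussianFit-class], [TwoSegmentFit-class],
#' [KelvinVoigtParams-class]) or plain lists to a JSON file.
#'
#' @param fit the object to serialize.
#' @param path file path.
#' @export
writeFitJSON <- function(fit, path) {
  x <- if (isVirtualClass(class(fit)) || !isS4(fit)) fit else {
    sl <- slotNames(class(fit))
    stats::setNames(lapply(sl, function(s) slot(fit, s)), sl)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
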