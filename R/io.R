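#' Write a FOV stack as a multi-page 32-bit float TIFF
#'
#' TIFF floats are stored on a [0, 1] scale; the affine normalization
#' (offset and scale) is written to a \code{<path>.json} sidecar so that
#' \code{\link{readStackTiff}} restores the original intensities.
#'
#' @param stack a \code{\linkS4class{FOVStack}}.
#' @param path output path.
#' @export
writeStackTiff <- function(stack, path) {
  imgs <- fovImages(stack)
  offset <- min(imgs)
  scale <- max(imgs) - offset
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(imgs)[3]),
                  function(f) (imgs[, , f] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = offset, scale = scale,
                            fov_ids = stack@fovIds),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF as a FOV stack
#'
#' If a \code{<path>.json} sidecar written by \code{\link{writeStackTiff}} is
#' present, the affine normalization is undone; otherwise values are read
#' as stored.
#'
#' @param path TIFF path.
#' @return a \code{\linkS4class{FOVStack}}.
#' @export
readStackTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) a[, , f] <- pages[[f]]
  fovIds <- seq_along(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    s <- jsonlite::read_json(side, simplifyVector = TRUE)
    a <- a * s$scale + s$offset
    if (!is.null(s$fov_ids)) fovIds <- as.integer(s$fov_ids)
  }
  new("FOVStack", images = a, fovIds = fovIds,
      metadata = list(source = path))
}

#' Write crops as a multi-page TIFF plus index CSV
#'
#' @param crops a \code{\linkS4class{CropSet}}.
#' @param tiffPath output TIFF (pages = crops, denoised channel).
#' @param indexPath output CSV linking pages to anchor localizations.
#' @param which crop channel to write.
#' @export
writeCrops <- function(crops, tiffPath, indexPath, which = "denoised") {
  a <- cropArray(crops, which)
  offset <- min(a)
  scale <- max(a) - offset
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(a)[3]), function(i) (a[, , i] - offset) / scale)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = offset, scale = scale),
                       paste0(tiffPath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  info <- cropInfo(crops)
  info$page <- seq_len(nrow(info))
  write.csv(info, indexPath, row.names = FALSE)
  invisible(tiffPath)
}

#' Write / read a localization table
#'
#' Columns \code{fov_id,row,col,intensity,sigma}; coordinates are 0-based
#' subpixel floats with row along the dispersion axis.
#'
#' @param locs localization data.frame.
#' @param path CSV path.
#' @export
writeLocalizationsCsv <- function(locs, path) {
  write.csv(locs[, c("fov_id", "row", "col", "intensity", "sigma")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writeLocalizationsCsv
#' @export
readLocalizationsCsv <- function(path) read.csv(path)

#' Write / read a confusion matrix CSV
#'
#' Square CSV with class names as header row and column.
#'
#' @param C confusion matrix.
#' @param path CSV path.
#' @export
writeConfusionCsv <- function(C, path) {
  write.csv(as.data.frame(C), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeConfusionCsv
#' @export
readConfusionCsv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write a ratio estimate report as JSON
#'
#' @param est a \code{\linkS4class{RatioEstimate}}.
#' @param path JSON path.
#' @export
writeRatioJson <- function(est, path) {
  obj <- list(composition = as.list(composition(est)),
              half_widths = as.list(halfWidths(est)),
              mean_2d = est@mean2d,
              covariance_2d = est@cov2d,
              reps = est@reps, count_cv = est@countCv, seed = est@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
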