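#' Detect diffraction-limited blobs in one image
#'
#' Band-pass (difference-of-Gaussians) filtering, local-maximum candidate
#' selection above a robust threshold (k MADs above the filtered image's
#' median — a statistical stand-in for manually tuned localization
#' thresholds), and 2-D Gaussian least-squares refinement for subpixel
#' position.  Fits whose width collapses below a single-pixel floor are
#' rejected, excluding single-pixel localizations.
#'
#' @param image 2-D numeric matrix.
#' @param kMad threshold in robust noise units (default 5).
#' @param sigma1,sigma2 difference-of-Gaussians scales in pixels.
#' @param fitRadius half-size of the square fit window.
#' @param sigmaFloor reject fits with sigma below this (single-pixel floor).
#' @return data.frame with columns \code{row, col} (0-based subpixel),
#'   \code{intensity} (fitted amplitude) and \code{sigma}.
#' @export
detectBlobs <- function(image, kMad = 5, sigma1 = 1.15, sigma2 = 2.3,
                        fitRadius = 3, sigmaFloor = 0.7) {
  stopifnot(is.matrix(image))
  empty <- data.frame(row = numeric(), col = numeric(),
                      intensity = numeric(), sigma = numeric())
  if (all(image == image[1])) return(empty)
  dog <- gaussianBlur(image, sigma1) - gaussianBlur(image, sigma2)
  thr <- median(dog) + kMad * mad(dog)
  nr <- nrow(dog); nc <- ncol(dog)
  inner <- dog[2:(nr - 1), 2:(nc - 1)]
  isMax <- inner > thr &
    inner >= dog[1:(nr - 2), 2:(nc - 1)] & inner > dog[3:nr, 2:(nc - 1)] &
    inner >= dog[2:(nr - 1), 1:(nc - 2)] & inner > dog[2:(nr - 1), 3:nc] &
    inner >= dog[1:(nr - 2), 1:(nc - 2)] & inner > dog[3:nr, 3:nc] &
    inner >= dog[1:(nr - 2), 3:nc] & inner > dog[3:nr, 1:(nc - 2)]
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  idx <- idx + 1L   # back to full-image indices
  fits <- lapply(seq_len(nrow(idx)), function(i)
    .fitGaussian2d(image, idx[i, 1], idx[i, 2], fitRadius))
  fits <- do.call(rbind, fits)
  keep <- !is.na(fits$sigma) & fits$sigma >= sigmaFloor & fits$intensity > 0
  fits[keep, , drop = FALSE]
}

# Gauss-Newton least-squares fit of A*exp(-((r-r0)^2+(c-c0)^2)/(2 s^2)) + b
# on a small window around an integer peak.  Returns 0-based subpixel
# coordinates; NA sigma on failure.
.fitGaussian2d <- function(image, r, c, radius = 3, sigmaInit = 1.15) {
  nr <- nrow(image); nc <- ncol(image)
  rr <- max(1, r - radius):min(nr, r + radius)
  cc <- max(1, c - radius):min(nc, c + radius)
  w <- image[rr, cc]
  R <- as.vector(row(w)) + rr[1] - 1
  C <- as.vector(col(w)) + cc[1] - 1
  y <- as.vector(w)
  b <- min(y)
  p <- c(A = max(y) - b, r0 = r, c0 = c, s = sigmaInit, b = b)
  lambda <- 1e-3
  for (it in 1:12) {
    dr <- R - p[2]; dc <- C - p[3]
    q <- (dr^2 + dc^2) / (2 * p[4]^2)
    E <- exp(-q)
    fit <- p[1] * E + p[5]
    res <- fit - y
    J <- cbind(E, p[1] * E * dr / p[4]^2, p[1] * E * dc / p[4]^2,
               p[1] * E * (dr^2 + dc^2) / p[4]^3, 1)
    H <- crossprod(J) + lambda * diag(5)
    g <- crossprod(J, res)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(data.frame(row = NA_real_, col = NA_real_,
                                         intensity = NA_real_, sigma = NA_real_))
    p <- p - as.vector(step)
    p[4] <- min(max(p[4], 0.3), 6)
    if (max(abs(step[2:3])) < 1e-4) break
  }
  # reject fits that ran away from the candidate pixel
  if (!all(is.finite(p)) || abs(p[2] - r) > radius || abs(p[3] - c) > radius)
    return(data.frame(row = NA_real_, col = NA_real_, intensity = NA_real_,
                      sigma = NA_real_))
  data.frame(row = p[2] - 1, col = p[3] - 1, intensity = p[1], sigma = p[4])
}

#' Detect blobs in every FOV of a stack
#'
#' @param stack a \code{\linkS4class{FOVStack}}.
#' @param ... passed to \code{\link{detectBlobs}}.
#' @return data.frame of localizations with a \code{fov_id} column.
#' @export
detectStack <- function(stack, ...) {
  stopifnot(is(stack, "FOVStack"))
  imgs <- fovImages(stack)
  out <- lapply(seq_len(dim(imgs)[3]), function(f) {
    df <- detectBlobs(imgs[, , f], ...)
    if (nrow(df)) cbind(fov_id = stack@fovIds[f], df) else
      cbind(fov_id = integer(), df)
  })
  do.call(rbind, out)
}

#' Merge near-duplicate localizations and discard boundary blobs
#'
#' Localizations closer than \code{dMerge} within one FOV are grouped by
#' single linkage and replaced by their mean position (iterated until stable,
#' so merging is idempotent).  Localizations whose 24 x 10 crop box would
#' leave the FOV are then discarded.
#'
#' @param locs localization data.frame (\code{fov_id, row, col, intensity,
#'   sigma}).
#' @param dMerge merge distance in pixels (default 2).
#' @param fovShape c(rows, cols) of the FOVs.
#' @param panelMinDistance optional minimum interspot distance of the barcode
#'   panel; \code{dMerge} at or above it would fuse the two spots of one
#'   barcode and is an error.
#' @return filtered localization data.frame.
#' @export
mergeAndFilter <- function(locs, dMerge = 2, fovShape,
                           panelMinDistance = NULL) {
  if (!is.null(panelMinDistance) && dMerge >= panelMinDistance)
    stop("merge would fuse barcode spots: dMerge (", dMerge,
         ") >= minimum panel interspot distance (",
         round(panelMinDistance, 2), ")")
  if (!nrow(locs)) return(locs)
  mergeOnce <- function(df) {
    if (nrow(df) < 2) return(df)
    cl <- stats::cutree(stats::hclust(stats::dist(df[, c("row", "col")]),
                                      method = "single"),
                        h = dMerge * (1 - 1e-9))
    if (max(cl) == nrow(df)) return(df)
    out <- lapply(split(df, cl), function(g)
      data.frame(fov_id = g$fov_id[1], row = mean(g$row), col = mean(g$col),
                 intensity = max(g$intensity), sigma = mean(g$sigma)))
    do.call(rbind, out)
  }
  merged <- lapply(split(locs, locs$fov_id), function(df) {
    repeat {
      out <- mergeOnce(df)
      if (nrow(out) == nrow(df)) return(out)
      df <- out
    }
  })
  merged <- do.call(rbind, merged)
  rownames(merged) <- NULL
  r0 <- round(merged$row) - 2
  c0 <- round(merged$col - 4.5)
  ok <- r0 >= 0 & r0 + 23 <= fovShape[1] - 1 & c0 >= 0 & c0 + 9 <= fovShape[2] - 1
  merged[ok, , drop = FALSE]
}

#' Extract 24 x 10 crops around localizations
#'
#' Crops are anchored with the blob at row index 2 and the columns centred so
#' that columns 4-5 straddle the blob (all 0-based).  Both the noisy
#' (median-subtracted) and the denoised stacks are cropped; both the lower
#' and the upper blob of a molecule yield crops, but only top-blob crops
#' contain the full dual-spot barcode.
#'
#' @param noisyStack,denoisedStack matching \code{\linkS4class{FOVStack}}s.
#' @param locs boundary-filtered localization data.frame.
#' @return a \code{\linkS4class{CropSet}}; the number of out-of-bounds crops
#'   skipped is recorded in \code{attr(, "skipped")}.
#' @export
extractCrops <- function(noisyStack, denoisedStack, locs) {
  stopifnot(is(noisyStack, "FOVStack"), is(denoisedStack, "FOVStack"))
  nImgs <- fovImages(noisyStack)
  dImgs <- fovImages(denoisedStack)
  stopifnot(identical(dim(nImgs), dim(dImgs)))
  fovIndex <- match(locs$fov_id, noisyStack@fovIds)
  r0 <- round(locs$row) - 2
  c0 <- round(locs$col - 4.5)
  ok <- !is.na(fovIndex) & r0 >= 0 & r0 + 23 <= dim(nImgs)[1] - 1 &
    c0 >= 0 & c0 + 9 <= dim(nImgs)[2] - 1
  skipped <- sum(!ok)
  idx <- which(ok)
  noisy <- array(0, c(24, 10, length(idx)))
  den <- array(0, c(24, 10, length(idx)))
  for (j in seq_along(idx)) {
    i <- idx[j]
    rows <- (r0[i] + 1):(r0[i] + 24)
    cols <- (c0[i] + 1):(c0[i] + 10)
    noisy[, , j] <- nImgs[rows, cols, fovIndex[i]]
    den[, , j] <- dImgs[rows, cols, fovIndex[i]]
  }
  info <- data.frame(fov_id = locs$fov_id[idx], row = locs$row[idx],
                     col = locs$col[idx], intensity = locs$intensity[idx],
                     sigma = locs$sigma[idx], crop_row0 = r0[idx],
                     crop_col0 = c0[idx])
  rownames(info) <- NULL
  out <- new("CropSet", noisy = noisy, denoised = den, info = info)
  attr(out, "skipped") <- skipped
  out
}

#' Label crops from synthetic ground truth
#'
#' Deterministic stand-in for visual tagging: a crop receives a molecule's
#' class iff its anchor localization lies within \code{tol} pixels of that
#' molecule's top-blob truth position; every other crop (bottom blobs,
#' spurious blobs, false detections) is labeled \code{"noise"}.
#'
#' @param crops a \code{\linkS4class{CropSet}}.
#' @param gt the scene's \code{\linkS4class{GroundTruth}}.
#' @param tol matching tolerance in pixels (default 1).
#' @return character vector of labels, one per crop.
#' @export
labelCropsFromTruth <- function(crops, gt, tol = 1) {
  info <- cropInfo(crops)
  rec <- truthRecords(gt)
  rec <- rec[rec$class_label != "spurious", ]
  labels <- rep("noise", nrow(info))
  for (f in unique(info$fov_id)) {
    ci <- which(info$fov_id == f)
    rf <- rec[rec$fov_id == f, ]
    if (!nrow(rf)) next
    for (i in ci) {
      d2 <- (rf$row - info$row[i])^2 + (rf$col - info$col[i])^2
      j <- which.min(d2)
      if (d2[j] <= tol^2) labels[i] <- rf$class_label[j]
    }
  }
  labels
}
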