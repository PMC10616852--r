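#' Pixel-wise median background of a stack
#'
#' The per-pixel median across the FOV axis; with sparse molecules this is the
#' (shared) background and is robust to bright artifacts in individual FOVs.
#'
#' @param stack a \code{\linkS4class{FOVStack}} or 3-D array (rows x cols x
#'   n_fov).
#' @return background matrix (rows x cols).
#' @export
medianBackground <- function(stack) {
  a <- if (is(stack, "FOVStack")) fovImages(stack) else stack
  if (dim(a)[3] < 3L)
    stop("need at least 3 FOVs for a meaningful pixel-wise median")
  .pixelwiseMedian(a)
}

#' Subtract the pixel-wise median background
#'
#' @param stack a \code{\linkS4class{FOVStack}}.
#' @return the median-subtracted stack.
#' @export
subtractBackground <- function(stack) {
  stopifnot(is(stack, "FOVStack"))
  bg <- medianBackground(stack)
  imgs <- fovImages(stack)
  imgs <- imgs - as.vector(bg)   # recycles over the FOV axis
  meta <- stack@metadata
  meta$medianSubtracted <- TRUE
  new("FOVStack", images = imgs, fovIds = stack@fovIds, metadata = meta)
}

#' Prune outlier FOVs from a median-subtracted stack
#'
#' For each FOV two rough statistics are computed: the mean of the positive
#' pixels and the absolute mean of the negative pixels.  Their maximum is
#' thresholded at the \code{keepFraction} quantile so that about that fraction
#' of FOVs is kept (exactly \code{ceiling(keepFraction * n)} up to ties,
#' broken by FOV index); FOVs with extreme features such as bubbles or a
#' background that disagrees with the median are dropped.
#'
#' @param stack a median-subtracted \code{\linkS4class{FOVStack}}.
#' @param keepFraction target fraction of FOVs to keep, in (0, 1].
#' @return list with elements \code{stack} (pruned) and \code{report}
#'   (data.frame with per-FOV statistics, threshold and keep flag).
#' @export
subtractAndPrune <- function(stack, keepFraction = 0.8) {
  stopifnot(is(stack, "FOVStack"))
  if (!is.numeric(keepFraction) || keepFraction <= 0 || keepFraction > 1)
    stop("keepFraction must lie in (0, 1]")
  if (is.null(stack@metadata$medianSubtracted))
    stack <- subtractBackground(stack)
  imgs <- fovImages(stack)
  n <- dim(imgs)[3]
  posMean <- negMeanAbs <- numeric(n)
  for (f in seq_len(n)) {
    v <- imgs[, , f]
    p <- v[v > 0]; q <- v[v < 0]
    posMean[f] <- if (length(p)) mean(p) else 0
    negMeanAbs[f] <- if (length(q)) abs(mean(q)) else 0
  }
  s <- pmax(posMean, negMeanAbs)
  nKeep <- ceiling(keepFraction * n)
  ord <- order(s, seq_len(n))
  keepIdx <- sort(ord[seq_len(nKeep)])
  threshold <- s[ord[nKeep]]
  report <- data.frame(fov_id = stack@fovIds, pos_mean = posMean,
                       neg_mean_abs = negMeanAbs, stat = s,
                       keep = seq_len(n) %in% keepIdx,
                       threshold = threshold, keep_fraction = keepFraction)
  pruned <- new("FOVStack", images = imgs[, , keepIdx, drop = FALSE],
                fovIds = stack@fovIds[keepIdx], metadata = stack@metadata)
  list(stack = pruned, report = report)
}

.DENOISE_METHODS <- c("none", "gaussian", "median", "external")

#' Denoise a stack
#'
#' A pluggable denoising slot.  \code{"none"} is the identity (the pipeline is
#' fully functional without denoising); \code{"gaussian"} and \code{"median"}
#' are small-kernel smoothers; \code{"external"} applies a user function with
#' an array-in/array-out contract (one FOV matrix in, same-shape matrix out),
#' the hook through which a learned denoiser can be plugged in.
#'
#' @param stack a \code{\linkS4class{FOVStack}}.
#' @param method one of \code{"none"}, \code{"gaussian"}, \code{"median"},
#'   \code{"external"}.
#' @param sigma Gaussian kernel SD in pixels (gaussian method).
#' @param size odd window size (median method).
#' @param fun function(matrix) -> matrix for the external method.
#' @return the denoised stack.
#' @export
denoiseStack <- function(stack, method = "none", sigma = 0.7, size = 3,
                         fun = NULL) {
  stopifnot(is(stack, "FOVStack"))
  if (!method %in% .DENOISE_METHODS)
    stop("unknown denoise method '", method, "'; available: ",
         paste(.DENOISE_METHODS, collapse = ", "))
  if (method == "none") return(stack)
  imgs <- fovImages(stack)
  out <- imgs
  for (f in seq_len(dim(imgs)[3])) {
    out[, , f] <- switch(method,
      gaussian = gaussianBlur(imgs[, , f], sigma),
      median = .medianFilter(imgs[, , f], size),
      external = {
        if (!is.function(fun)) stop("method 'external' needs a function")
        m <- fun(imgs[, , f])
        if (!identical(dim(m), dim(imgs[, , f])))
          stop("external denoiser changed the image shape")
        m
      })
  }
  meta <- stack@metadata
  meta$denoise <- method
  new("FOVStack", images = out, fovIds = stack@fovIds, metadata = meta)
}

# square median filter with edge replication
.medianFilter <- function(m, size = 3) {
  stopifnot(size %% 2 == 1)
  h <- (size - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(outer(seq_len(nr), -h:h, `+`), 1), nr)
  ci <- pmin(pmax(outer(seq_len(nc), -h:h, `+`), 1), nc)
  shifted <- array(NA_real_, c(nr, nc, size * size))
  k <- 0
  for (i in seq_len(size)) for (j in seq_len(size)) {
    k <- k + 1
    shifted[, , k] <- m[ri[, i], ci[, j]]
  }
  .pixelwiseMedian(shifted)
}

#' Full image preprocessing: background, pruning, denoising
#'
#' Convenience wrapper running the three preprocessing steps in order:
#' pixel-wise median subtraction, outlier-FOV pruning at the target keep
#' fraction, and the denoising slot.
#'
#' @param stack raw \code{\linkS4class{FOVStack}}.
#' @param keepFraction FOV keep fraction (default 0.8).
#' @param denoise denoise method (default \code{"gaussian"}).
#' @param ... passed to \code{\link{denoiseStack}}.
#' @return list with \code{noisy} (median-subtracted, pruned),
#'   \code{denoised}, \code{background} and \code{report}.
#' @export
preprocessStack <- function(stack, keepFraction = 0.8, denoise = "gaussian",
                            ...) {
  bg <- medianBackground(stack)
  sub <- subtractBackground(stack)
  pr <- subtractAndPrune(sub, keepFraction)
  den <- denoiseStack(pr$stack, method = denoise, ...)
  list(noisy = pr$stack, denoised = den, background = bg, report = pr$report)
}
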