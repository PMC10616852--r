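#' @import methods
#' @importFrom stats median mad prcomp predict quantile rnorm rpois rmultinom
#'   sd splinefun approx var
#' @importFrom utils read.csv write.csv head
NULL

# Internal wavelength grid shared by all spectral fixtures (1 nm step).
.WL_GRID <- seq(400, 850, by = 1)

#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed deterministically
#' from one global seed, so that a single integer reproduces a whole run.
#' Seeds stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed for the stage.
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Separable Gaussian blur with edge renormalisation.  Implemented as two
# banded-matrix products; for the 256-pixel fields used here this is faster
# than FFT once kernel construction is cached.
.blurBand <- function(n, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  B <- matrix(0, n, n)
  for (d in -h:h) {
    idx <- seq_len(n - abs(d))
    if (d >= 0) B[cbind(idx, idx + d)] <- k[d + h + 1]
    else B[cbind(idx - d, idx)] <- k[d + h + 1]
  }
  B / rowSums(B)
}

#' Gaussian blur of a matrix
#'
#' @param m numeric matrix.
#' @param sigma blur standard deviation in pixels.
#' @return blurred matrix of the same shape.
#' @export
gaussianBlur <- function(m, sigma) {
  stopifnot(is.matrix(m), sigma > 0)
  Br <- .blurBand(nrow(m), sigma)
  Bc <- .blurBand(ncol(m), sigma)
  Br %*% m %*% t(Bc)
}

# median across the third (FOV) axis of a stack array
.pixelwiseMedian <- function(a) {
  d <- dim(a)
  m <- a
  dim(m) <- c(d[1] * d[2], d[3])
  out <- apply(m, 1, median)
  dim(out) <- d[1:2]
  out
}

.isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
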