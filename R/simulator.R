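#' Emission spectrum seen through the filter
#'
#' Pointwise product of a dye's emission curve and the filter transmission on
#' the shared wavelength grid — the spectrum actually visible on the camera.
#'
#' @param spec a \code{\linkS4class{FluorophoreSpectrum}}.
#' @param filt a \code{\linkS4class{FilterCurve}}.
#' @return numeric vector of filtered emission on the internal grid.
#' @export
effectiveEmission <- function(spec, filt) {
  stopifnot(is(spec, "FluorophoreSpectrum"), is(filt, "FilterCurve"))
  out <- spec@emission * filt@transmission
  if (sum(spec@emission) > 0 && sum(filt@transmission) > 0 && all(out == 0))
    stop("no spectral overlap between emission and filter transmission")
  out
}

#' Adjust a dispersion curve to a relative prism angle
#'
#' The whole reference calibration curve is scaled by
#' sin((180 - RPA) / 2) (angle in degrees): co-rotating the prisms toward
#' 180 degrees cancels the dispersion.
#'
#' @param curve reference \code{\linkS4class{DispersionCurve}}.
#' @param rpaDeg relative prism angle in degrees, in (0, 180].
#' @return the scaled curve with \code{rpaDeg} recorded.
#' @export
rpaAdjust <- function(curve, rpaDeg) {
  stopifnot(is(curve, "DispersionCurve"))
  if (!is.numeric(rpaDeg) || length(rpaDeg) != 1L || rpaDeg <= 0 || rpaDeg > 180)
    stop("rpaDeg must lie in (0, 180]")
  factor <- sin((180 - rpaDeg) / 2 * pi / 180)
  new("DispersionCurve", wavelengths = curve@wavelengths,
      displacement = curve@displacement * factor, rpaDeg = rpaDeg)
}

# Per-wavelength Gaussian amplitudes for one dye: filtered emission scaled so
# the untruncated rendered image sums to the excitation efficiency.
# Returns list(d = displacements, a = 2-D Gaussian amplitudes, eff).
.dyeComponents <- function(spec, filt, curve, cfg) {
  em <- effectiveEmission(spec, filt)
  keep <- em > max(em) * 1e-6
  if (!any(keep)) keep <- em >= 0  # all-zero: handled by efficiency check
  # excitation efficiency at the laser line(s): maximum single-line value
  effs <- vapply(cfg@laserLines, function(l) {
    i <- which.min(abs(spec@wavelengths - l))
    spec@excitation[i]
  }, numeric(1))
  eff <- max(effs)
  tot <- sum(em[keep])
  a <- if (tot > 0) em[keep] / tot * eff / (2 * pi * cfg@sigmaPx^2) else em[keep]
  list(d = curve@displacement[keep], a = a, eff = eff,
       laser = cfg@laserLines[which.max(effs)])
}

# Row (dispersion-axis) profile of a set of Gaussian components evaluated at
# positions r: sum_l a_l * exp(-(r - d_l)^2 / (2 sigma^2)), truncated at 5
# sigma.
.rowProfile <- function(r, d, a, sigma) {
  out <- numeric(length(r))
  for (i in seq_along(d)) {
    dz <- r - d[i]
    inz <- abs(dz) <= 5 * sigma
    if (any(inz)) out[inz] <- out[inz] + a[i] * exp(-dz[inz]^2 / (2 * sigma^2))
  }
  out
}

.colKernel <- function(cols, anchorCol, sigma) {
  dz <- cols - anchorCol
  k <- exp(-dz^2 / (2 * sigma^2))
  k[abs(dz) > 5 * sigma] <- 0
  k
}

#' Render one fluorophore's dispersed image
#'
#' Every wavelength of the filtered emission spectrum contributes an isotropic
#' Gaussian (sd \code{sigmaPx}) displaced along the dispersion axis (rows) by
#' the calibration curve; the sum is normalised to unit total intensity and
#' multiplied by the excitation efficiency (the excitation fraction at the
#' laser line; with several lasers, the best single line).
#'
#' @param spec a \code{\linkS4class{FluorophoreSpectrum}}.
#' @param filt a \code{\linkS4class{FilterCurve}}.
#' @param curve an RPA-adjusted \code{\linkS4class{DispersionCurve}}.
#' @param cfg a \code{\linkS4class{SimulatorConfig}}.
#' @param anchor numeric c(row, col): 0-based position of the zero-dispersion
#'   origin in the patch. Defaults to row 2, column centre.
#' @param patchShape optional c(rows, cols) override of \code{cfg@patchShape}.
#' @return numeric patch matrix with attributes \code{efficiency} and
#'   \code{laser}.  The patch sums to the efficiency up to edge truncation.
#' @export
renderFluorophore <- function(spec, filt, curve, cfg = simulatorConfig(),
                              anchor = NULL, patchShape = NULL) {
  stopifnot(is(curve, "DispersionCurve"), is(cfg, "SimulatorConfig"))
  shape <- if (is.null(patchShape)) cfg@patchShape else as.integer(patchShape)
  if (is.null(anchor)) anchor <- c(2, (shape[2] - 1) / 2)
  comp <- .dyeComponents(spec, filt, curve, cfg)
  if (comp$eff <= 0) {
    warning("excitation efficiency is zero for all laser lines; returning a zero image")
    img <- matrix(0, shape[1], shape[2])
  } else {
    rows <- (seq_len(shape[1]) - 1) - anchor[1]
    prof <- .rowProfile(rows, comp$d, comp$a, cfg@sigmaPx)
    img <- outer(prof, .colKernel((seq_len(shape[2]) - 1), anchor[2], cfg@sigmaPx))
  }
  attr(img, "efficiency") <- comp$eff
  attr(img, "laser") <- comp$laser
  img
}

# locate profile peaks on a fine grid with 3-point parabolic refinement
.profilePeaks <- function(grid, value, relThreshold = 0.1, minSepPx = 1) {
  n <- length(value)
  isMax <- c(FALSE, value[2:(n - 1)] > value[1:(n - 2)] &
               value[2:(n - 1)] >= value[3:n], FALSE)
  idx <- which(isMax & value >= relThreshold * max(value))
  if (!length(idx)) return(data.frame(pos = numeric(), height = numeric()))
  # collapse maxima closer than minSepPx, keeping the higher one
  step <- grid[2] - grid[1]
  idx <- idx[order(-value[idx])]
  kept <- integer()
  for (i in idx)
    if (!length(kept) || all(abs(grid[i] - grid[kept]) >= minSepPx))
      kept <- c(kept, i)
  kept <- sort(kept)
  pos <- vapply(kept, function(i) {
    if (i <= 1 || i >= n) return(grid[i])
    y0 <- value[i - 1]; y1 <- value[i]; y2 <- value[i + 1]
    den <- y0 - 2 * y1 + y2
    if (den == 0) grid[i] else grid[i] + 0.5 * step * (y0 - y2) / den
  }, numeric(1))
  data.frame(pos = pos, height = value[kept])
}

#' Render a dual-fluorophore spectral barcode
#'
#' The two single-dye images are summed pixelwise; the interspot distance is
#' measured by subpixel peak finding on the dispersion-axis profile.  The
#' stored patch is anchored on the top (shortest-wavelength) blob at row 2,
#' column centre.
#'
#' @param classLabel class carried by the barcode.
#' @param dyeA,dyeB \code{\linkS4class{FluorophoreSpectrum}} objects (or
#'   fixture dye names).
#' @param filt a \code{\linkS4class{FilterCurve}}.
#' @param curve an RPA-adjusted \code{\linkS4class{DispersionCurve}}.
#' @param cfg a \code{\linkS4class{SimulatorConfig}}.
#' @return a \code{\linkS4class{SpectralBarcode}}.
#' @export
renderPair <- function(classLabel, dyeA, dyeB, filt, curve,
                       cfg = simulatorConfig()) {
  if (is.character(dyeA)) dyeA <- fixtureDye(dyeA)
  if (is.character(dyeB)) dyeB <- fixtureDye(dyeB)
  ca <- .dyeComponents(dyeA, filt, curve, cfg)
  cb <- .dyeComponents(dyeB, filt, curve, cfg)
  d <- c(ca$d, cb$d)
  a <- c(ca$a, cb$a)
  if (ca$eff <= 0 || cb$eff <= 0)
    warning("one of the dyes has zero excitation efficiency")
  # fine profile along the dispersion axis, wide enough for the full spread
  grid <- seq(min(d) - 6 * cfg@sigmaPx, max(d) + 6 * cfg@sigmaPx, by = 0.02)
  prof <- .rowProfile(grid, d, a, cfg@sigmaPx)
  pk <- .profilePeaks(grid, prof)
  dist <- if (nrow(pk) < 2) 0 else {
    top2 <- pk[order(-pk$height), ][1:2, ]
    abs(diff(sort(top2$pos)))
  }
  topPos <- if (nrow(pk) < 2) pk$pos[which.max(pk$height)] else
    min(pk[order(-pk$height), ][1:2, "pos"])
  shape <- cfg@patchShape
  anchorRow <- 2; anchorCol <- (shape[2] - 1) / 2
  rows <- (seq_len(shape[1]) - 1) - anchorRow + topPos
  prows <- .rowProfile(rows, d, a, cfg@sigmaPx)
  psf <- outer(prows, .colKernel(seq_len(shape[2]) - 1, anchorCol, cfg@sigmaPx))
  new("SpectralBarcode", classLabel = classLabel, dyeA = dyeA, dyeB = dyeB,
      psf = psf, interspotDistance = dist,
      profile = list(grid = grid - topPos, value = prof),
      efficiency = ca$eff + cb$eff)
}

#' Add the camera noise model to an image
#'
#' Poisson shot noise (sampled at \code{poissonScale} photons per intensity
#' unit, rescaled back) plus additive Gaussian noise with mean
#' \code{noiseGaussianMean} and variance \code{noiseGaussianVar}.
#'
#' @param img non-negative numeric matrix.
#' @param cfg a \code{\linkS4class{SimulatorConfig}}.
#' @param seed optional integer seed; for a fixed seed the output is
#'   deterministic.
#' @return noisy image of the same shape.
#' @export
addNoise <- function(img, cfg = simulatorConfig(), seed = NULL) {
  if (any(img < -1e-9)) stop("image must be non-negative")
  if (cfg@noiseGaussianVar < 0) stop("noise variance must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  out <- img
  if (cfg@poissonScale > 0)
    out[] <- rpois(length(img), pmax(img, 0) * cfg@poissonScale) / cfg@poissonScale
  out + matrix(rnorm(length(img), cfg@noiseGaussianMean,
                     sqrt(cfg@noiseGaussianVar)), nrow(img), ncol(img))
}

#' Build a barcode panel from dye pairs
#'
#' @param pairs list of \code{list(classLabel=, dyeA=, dyeB=)}; dyes may be
#'   fixture names or \code{FluorophoreSpectrum} objects.
#' @param filt emission filter (default \code{\link{fixtureFilter}}).
#' @param curve reference dispersion curve (default
#'   \code{\link{fixtureDispersion}}).
#' @param rpaDeg relative prism angle, degrees (default 177.5).
#' @param cfg a \code{\linkS4class{SimulatorConfig}}.
#' @return a \code{\linkS4class{BarcodePanel}}.
#' @export
buildPanel <- function(pairs, filt = fixtureFilter(),
                       curve = fixtureDispersion(), rpaDeg = 177.5,
                       cfg = simulatorConfig()) {
  adj <- if (is.na(curve@rpaDeg)) rpaAdjust(curve, rpaDeg) else curve
  barcodes <- lapply(pairs, function(p)
    renderPair(p$classLabel, p$dyeA, p$dyeB, filt, adj, cfg))
  new("BarcodePanel", barcodes = barcodes, filter = filt, dispersion = adj,
      config = cfg)
}

#' Default three-target demonstration panel
#'
#' Three dual-dye barcodes sharing a common short-wavelength dye, yielding
#' three well-separated interspot distances at RPA 177.5 degrees.
#'
#' @param rpaDeg relative prism angle, degrees.
#' @param cfg a \code{\linkS4class{SimulatorConfig}}.
#' @return a \code{\linkS4class{BarcodePanel}}.
#' @export
defaultPanel <- function(rpaDeg = 177.5, cfg = simulatorConfig()) {
  buildPanel(list(
    list(classLabel = "miR-15b", dyeA = "af405", dyeB = "af488"),
    list(classLabel = "miR-155", dyeA = "af405", dyeB = "af568"),
    list(classLabel = "miR-126", dyeA = "af405", dyeB = "af647")),
    rpaDeg = rpaDeg, cfg = cfg)
}

#' Pairwise distinguishability of a barcode panel
#'
#' Tabulates the absolute interspot-distance gap between every pair of
#' barcodes and flags pairs whose gap falls below a minimum (default twice
#' the PSF standard deviation).
#'
#' @param panel a \code{\linkS4class{BarcodePanel}} or list of barcodes.
#' @param minGap minimum resolvable distance gap in pixels.
#' @return data.frame with columns \code{class_a, class_b, gap_px, flagged}.
#' @export
panelDistinctness <- function(panel, minGap = NULL) {
  barcodes <- if (is(panel, "BarcodePanel")) panel@barcodes else panel
  if (length(barcodes) < 2L) stop("need at least two barcodes")
  if (is.null(minGap))
    minGap <- 2 * (if (is(panel, "BarcodePanel")) panel@config@sigmaPx else 1.15)
  labs <- vapply(barcodes, function(b) b@classLabel, character(1))
  d <- vapply(barcodes, function(b) b@interspotDistance, numeric(1))
  cmb <- utils::combn(length(barcodes), 2)
  data.frame(class_a = labs[cmb[1, ]], class_b = labs[cmb[2, ]],
             gap_px = abs(d[cmb[1, ]] - d[cmb[2, ]]),
             flagged = abs(d[cmb[1, ]] - d[cmb[2, ]]) < minGap)
}
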