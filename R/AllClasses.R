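#' FluorophoreSpectrum: excitation and emission spectrum of one dye
#'
#' Holds excitation and emission curves of a fluorophore on a shared ascending
#' wavelength grid (nanometres).  Excitation values are fractions in [0, 1];
#' emission is non-negative and unitless (shape only — the renderer normalises
#' total intensity).
#'
#' @slot name dye label.
#' @slot wavelengths ascending wavelength grid in nm.
#' @slot excitation excitation fraction per wavelength, in [0, 1].
#' @slot emission emission intensity per wavelength, >= 0.
#' @export
setClass("FluorophoreSpectrum",
  representation(name = "character", wavelengths = "numeric",
                 excitation = "numeric", emission = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@wavelengths)
    if (n < 2L || is.unsorted(object@wavelengths, strictly = TRUE))
      msg <- c(msg, "wavelengths must be a strictly ascending grid")
    if (length(object@excitation) != n || length(object@emission) != n)
      msg <- c(msg, "excitation and emission must share the wavelength grid")
    if (!all(is.finite(object@excitation)) || !all(is.finite(object@emission)))
      msg <- c(msg, "spectra must be finite")
    if (any(object@excitation < 0) || any(object@excitation > 1))
      msg <- c(msg, "excitation must lie in [0, 1]")
    if (any(object@emission < 0))
      msg <- c(msg, "emission must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' FilterCurve: transmission of the emission filter
#'
#' @slot wavelengths ascending wavelength grid in nm.
#' @slot transmission transmission fraction per wavelength, in [0, 1].
#' @export
setClass("FilterCurve",
  representation(wavelengths = "numeric", transmission = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@wavelengths, strictly = TRUE))
      msg <- c(msg, "wavelengths must be strictly ascending")
    if (length(object@transmission) != length(object@wavelengths))
      msg <- c(msg, "transmission must share the wavelength grid")
    if (any(!is.finite(object@transmission)) ||
        any(object@transmission < 0) || any(object@transmission > 1))
      msg <- c(msg, "transmission must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' DispersionCurve: wavelength to pixel displacement calibration
#'
#' Maps emission wavelength to displacement (pixels) along the dispersion axis
#' (image rows, displacement increasing downward with wavelength).  A curve is
#' measured at a reference prism angle; \code{\link{rpaAdjust}} scales it to
#' the relative prism angle (RPA) actually used and records that angle in
#' \code{rpaDeg} (NA for an unadjusted reference curve).
#'
#' @slot wavelengths ascending wavelength grid in nm.
#' @slot displacement pixel displacement per wavelength, non-decreasing.
#' @slot rpaDeg relative prism angle in degrees (NA until adjusted).
#' @export
setClass("DispersionCurve",
  representation(wavelengths = "numeric", displacement = "numeric",
                 rpaDeg = "numeric"),
  prototype(rpaDeg = NA_real_),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@wavelengths, strictly = TRUE))
      msg <- c(msg, "wavelengths must be strictly ascending")
    if (length(object@displacement) != length(object@wavelengths))
      msg <- c(msg, "displacement must share the wavelength grid")
    if (any(!is.finite(object@displacement)))
      msg <- c(msg, "displacement must be finite")
    if (is.unsorted(object@displacement))
      msg <- c(msg, "displacement must be monotonically non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' SimulatorConfig: rendering and noise parameters
#'
#' @slot sigmaPx per-wavelength Gaussian standard deviation in pixels
#'   (default 1.15).
#' @slot laserLines excitation laser wavelengths in nm.
#' @slot patchShape rows x cols of a rendered patch (default 24 x 10).
#' @slot noiseGaussianMean additive Gaussian offset (default 0.3).
#' @slot noiseGaussianVar additive Gaussian variance.
#' @slot poissonScale photons per intensity unit for shot noise (0 disables).
#' @export
setClass("SimulatorConfig",
  representation(sigmaPx = "numeric", laserLines = "numeric",
                 patchShape = "integer", noiseGaussianMean = "numeric",
                 noiseGaussianVar = "numeric", poissonScale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@sigmaPx <= 0) msg <- c(msg, "sigmaPx must be positive")
    if (length(object@patchShape) != 2L || object@patchShape[1] < 24L ||
        object@patchShape[2] < 10L)
      msg <- c(msg, "patchShape must be at least 24 rows x 10 cols")
    if (object@noiseGaussianVar < 0) msg <- c(msg, "noise variance must be >= 0")
    if (object@poissonScale < 0) msg <- c(msg, "poissonScale must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' SpectralBarcode: a dual-fluorophore probe and its rendered PSF
#'
#' @slot classLabel target class carried by this barcode.
#' @slot dyeA,dyeB the two fluorophores.
#' @slot psf noiseless rendered dual-spot patch (top blob anchored).
#' @slot interspotDistance distance between the two blobs in pixels.
#' @slot profile fine-grained row (dispersion-axis) profile used for subpixel
#'   placement; a list with elements \code{grid} and \code{value}, the grid
#'   zeroed on the top-blob peak.
#' @slot efficiency summed excitation efficiency of the two dyes (the total
#'   intensity of the noiseless patch before truncation).
#' @export
setClass("SpectralBarcode",
  representation(classLabel = "character", dyeA = "FluorophoreSpectrum",
                 dyeB = "FluorophoreSpectrum", psf = "matrix",
                 interspotDistance = "numeric", profile = "list",
                 efficiency = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@psf < -1e-9)) msg <- c(msg, "rendered PSF must be non-negative")
    if (object@interspotDistance < 0) msg <- c(msg, "interspot distance must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' BarcodePanel: the set of barcodes used in one experiment
#'
#' @slot barcodes list of \code{SpectralBarcode}.
#' @slot filter the emission \code{FilterCurve}.
#' @slot dispersion the RPA-adjusted \code{DispersionCurve}.
#' @slot config the \code{SimulatorConfig} the panel was rendered with.
#' @export
setClass("BarcodePanel",
  representation(barcodes = "list", filter = "FilterCurve",
                 dispersion = "DispersionCurve", config = "SimulatorConfig"),
  validity = function(object) {
    ok <- vapply(object@barcodes, is, logical(1), class2 = "SpectralBarcode")
    if (!all(ok)) return("barcodes must be SpectralBarcode objects")
    labs <- vapply(object@barcodes, function(b) b@classLabel, character(1))
    if (anyDuplicated(labs)) return("class labels must be unique")
    TRUE
  })

#' GroundTruth: known molecule records of a synthetic scene
#'
#' One row per rendered object: true barcode class (or \code{"spurious"} for
#' single-blob distractors), field of view, top-blob anchor position (0-based
#' pixel coordinates, row = dispersion axis) and brightness multiplier.
#'
#' @slot records data.frame with columns \code{fov_id, class_label, row, col,
#'   brightness}.
#' @slot config scene configuration list (fov shape, margin, min separation,
#'   per-class counts, spurious rate, brightness distribution, seed).
#' @export
setClass("GroundTruth",
  representation(records = "data.frame", config = "list"),
  validity = function(object) {
    need <- c("fov_id", "class_label", "row", "col", "brightness")
    if (!all(need %in% names(object@records)))
      return(paste("records must have columns", paste(need, collapse = ", ")))
    TRUE
  })

#' FOVStack: a stack of field-of-view images
#'
#' @slot images 3-D numeric array, rows x cols x n_fov.
#' @slot fovIds integer ids of the retained FOVs (1-based).
#' @slot metadata free-form provenance list (seed, background model, ...).
#' @export
setClass("FOVStack",
  representation(images = "array", fovIds = "integer", metadata = "list"),
  validity = function(object) {
    if (length(dim(object@images)) != 3L) return("images must be a 3-D array")
    if (!all(is.finite(object@images))) return("images must be finite")
    if (length(object@fovIds) != dim(object@images)[3])
      return("fovIds must match the number of FOV pages")
    TRUE
  })

#' CropSet: 24 x 10 patches around detected blobs
#'
#' @slot noisy 24 x 10 x n array of crops from the median-subtracted stack.
#' @slot denoised matching array of crops from the denoised stack.
#' @slot info data.frame of anchor localizations: \code{fov_id, row, col,
#'   intensity, sigma, crop_row0, crop_col0} (0-based).
#' @export
setClass("CropSet",
  representation(noisy = "array", denoised = "array", info = "data.frame"),
  validity = function(object) {
    d <- dim(object@noisy)
    if (length(d) != 3L || d[1] != 24L || d[2] != 10L)
      return("crops must be 24 x 10 patches")
    if (!identical(dim(object@denoised), d))
      return("noisy and denoised arrays must have the same shape")
    if (nrow(object@info) != d[3])
      return("info must have one row per crop")
    TRUE
  })

#' PreparedCrops: preprocessed, symmetrized classifier inputs
#'
#' @slot halves n x 120 matrix of symmetrized half-crops (24 x 5, row-major
#'   flattened); rejected crops hold zeros.
#' @slot k per-crop normalization constant (mean of the four anchor pixels
#'   before normalization).
#' @slot rejected logical flag per crop.
#' @slot reason rejection reason ("" when kept).
#' @export
setClass("PreparedCrops",
  representation(halves = "matrix", k = "numeric", rejected = "logical",
                 reason = "character"),
  validity = function(object) {
    n <- nrow(object@halves)
    if (ncol(object@halves) != 120L) return("half-crops must have 120 values")
    if (length(object@k) != n || length(object@rejected) != n ||
        length(object@reason) != n)
      return("k, rejected and reason must have one entry per crop")
    TRUE
  })

#' CropFeatureModel: PCA basis and feature standardization
#'
#' Twenty principal components of the 120-value half-crops plus the
#' standardization statistics of the 21 features (20 PCA coefficients and the
#' normalization constant k).
#'
#' @slot rotation 120 x nComp orthonormal component matrix.
#' @slot center 120-long training mean of the half-crops.
#' @slot featCenter,featScale length-(nComp+1) standardization statistics.
#' @slot nComp number of components (default 20).
#' @export
setClass("CropFeatureModel",
  representation(rotation = "matrix", center = "numeric",
                 featCenter = "numeric", featScale = "numeric",
                 nComp = "integer"),
  validity = function(object) {
    if (ncol(object@rotation) != object@nComp)
      return("rotation must have nComp columns")
    G <- crossprod(object@rotation)
    if (max(abs(G - diag(object@nComp))) > 1e-6)
      return("components must be orthonormal")
    if (length(object@featCenter) != object@nComp + 1L ||
        length(object@featScale) != object@nComp + 1L)
      return("feature statistics must cover nComp coefficients plus k")
    TRUE
  })

#' BarcodeClassifier: the trained PCA + RBF-SVM model
#'
#' @slot svm fitted \code{e1071::svm} object (probability model enabled).
#' @slot featureModel the \code{CropFeatureModel} used to build features.
#' @slot classes class labels in fixed order; the last is \code{"noise"}.
#' @slot hyper hyperparameter list (cost, gamma, augmentation, seed, split).
#' @slot validation list with the held-out validation confusion matrix and
#'   accuracy.
#' @export
setClass("BarcodeClassifier",
  representation(svm = "ANY", featureModel = "CropFeatureModel",
                 classes = "character", hyper = "list", validation = "list"),
  validity = function(object) {
    if (length(object@classes) < 2L) return("need at least two classes")
    if (object@classes[length(object@classes)] != "noise")
      return("the last class must be 'noise'")
    TRUE
  })

#' RatioEstimate: calibrated mixture composition with uncertainty
#'
#' The corrected mixture composition over the target classes (noise class
#' excluded, entries summing to 1), with per-class 95% (two standard
#' deviation) half-widths from the resampling ensemble and the fitted 2-D
#' Gaussian on the simplex plane.
#'
#' @slot composition named composition vector (sums to 1).
#' @slot halfWidths per-class 2-SD half-widths on the composition scale
#'   (zero-length before \code{\link{estimateUncertainty}} is run).
#' @slot mean2d,cov2d fitted Gaussian mean and covariance in isometric
#'   simplex-plane coordinates.
#' @slot reps,countCv,seed resampling settings used.
#' @export
setClass("RatioEstimate",
  representation(composition = "numeric", halfWidths = "numeric",
                 mean2d = "numeric", cov2d = "matrix", reps = "integer",
                 countCv = "numeric", seed = "integer"),
  prototype(halfWidths = numeric(), mean2d = numeric(),
            cov2d = matrix(numeric(), 0, 0), reps = 0L, countCv = NA_real_,
            seed = NA_integer_),
  validity = function(object) {
    p <- object@composition
    if (any(p < -1e-9)) return("composition must be non-negative")
    if (abs(sum(p) - 1) > 1e-9) return("composition must sum to 1")
    if (length(object@halfWidths) &&
        (length(object@halfWidths) != length(p) || any(object@halfWidths < 0)))
      return("halfWidths must be non-negative, one per class")
    TRUE
  })
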