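#' @rdname interspotDistance
#' @export
setGeneric("interspotDistance", function(x) standardGeneric("interspotDistance"))

#' @rdname classLabels
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname nFov
#' @export
setGeneric("nFov", function(x) standardGeneric("nFov"))

#' @rdname fovImages
#' @export
setGeneric("fovImages", function(x) standardGeneric("fovImages"))

#' @rdname truthRecords
#' @export
setGeneric("truthRecords", function(x) standardGeneric("truthRecords"))

#' @rdname nCrops
#' @export
setGeneric("nCrops", function(x) standardGeneric("nCrops"))

#' @rdname cropInfo
#' @export
setGeneric("cropInfo", function(x) standardGeneric("cropInfo"))

#' @rdname cropArray
#' @export
setGeneric("cropArray", function(x, which = c("denoised", "noisy"))
  standardGeneric("cropArray"))

#' Interspot distance of a barcode
#'
#' @param x a \code{SpectralBarcode} or \code{BarcodePanel}.
#' @return distance(s) in pixels between the two blobs of the dual-spot PSF.
#' @rdname interspotDistance
#' @export
setMethod("interspotDistance", "SpectralBarcode", function(x) x@interspotDistance)

#' @rdname interspotDistance
#' @export
setMethod("interspotDistance", "BarcodePanel", function(x) {
  d <- vapply(x@barcodes, function(b) b@interspotDistance, numeric(1))
  names(d) <- classLabels(x)
  d
})

#' Class labels
#'
#' @param x a \code{BarcodePanel}, \code{GroundTruth} or
#'   \code{BarcodeClassifier}.
#' @return character vector of class labels.
#' @rdname classLabels
#' @export
setMethod("classLabels", "BarcodePanel", function(x)
  vapply(x@barcodes, function(b) b@classLabel, character(1)))

#' @rdname classLabels
#' @export
setMethod("classLabels", "BarcodeClassifier", function(x) x@classes)

#' @rdname classLabels
#' @export
setMethod("classLabels", "GroundTruth", function(x)
  setdiff(unique(x@records$class_label), "spurious"))

#' Number of fields of view
#'
#' @param x a \code{FOVStack} or \code{GroundTruth}.
#' @rdname nFov
#' @export
setMethod("nFov", "FOVStack", function(x) dim(x@images)[3])

#' @rdname nFov
#' @export
setMethod("nFov", "GroundTruth", function(x) x@config$nFov)

#' Image array of a stack
#'
#' @param x a \code{FOVStack}.
#' @return rows x cols x n_fov numeric array.
#' @rdname fovImages
#' @export
setMethod("fovImages", "FOVStack", function(x) x@images)

#' Ground-truth records
#'
#' @param x a \code{GroundTruth}.
#' @return data.frame of molecule records.
#' @rdname truthRecords
#' @export
setMethod("truthRecords", "GroundTruth", function(x) x@records)

#' Number of crops
#'
#' @param x a \code{CropSet} or \code{PreparedCrops}.
#' @rdname nCrops
#' @export
setMethod("nCrops", "CropSet", function(x) dim(x@noisy)[3])

#' @rdname nCrops
#' @export
setMethod("nCrops", "PreparedCrops", function(x) nrow(x@halves))

#' Crop anchor table
#'
#' @param x a \code{CropSet}.
#' @return data.frame of anchor localizations, one row per crop.
#' @rdname cropInfo
#' @export
setMethod("cropInfo", "CropSet", function(x) x@info)

#' Crop patch array
#'
#' @param x a \code{CropSet}.
#' @param which \code{"denoised"} (default) or \code{"noisy"}.
#' @return 24 x 10 x n array.
#' @rdname cropArray
#' @export
setMethod("cropArray", "CropSet", function(x, which = c("denoised", "noisy")) {
  which <- match.arg(which)
  if (which == "denoised") x@denoised else x@noisy
})

setMethod("show", "FluorophoreSpectrum", function(object) {
  exPk <- object@wavelengths[which.max(object@excitation)]
  emPk <- object@wavelengths[which.max(object@emission)]
  cat(sprintf("FluorophoreSpectrum '%s': ex peak %g nm, em peak %g nm, grid %g-%g nm\n",
              object@name, exPk, emPk, min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "DispersionCurve", function(object) {
  cat(sprintf("DispersionCurve: %g-%g nm -> %.2f-%.2f px%s\n",
              min(object@wavelengths), max(object@wavelengths),
              min(object@displacement), max(object@displacement),
              if (is.na(object@rpaDeg)) " (reference angle)"
              else sprintf(" at RPA %.1f deg", object@rpaDeg)))
})

setMethod("show", "SpectralBarcode", function(object) {
  cat(sprintf("SpectralBarcode '%s' (%s + %s): interspot distance %.2f px, efficiency %.3f\n",
              object@classLabel, object@dyeA@name, object@dyeB@name,
              object@interspotDistance, object@efficiency))
})

setMethod("show", "BarcodePanel", function(object) {
  cat(sprintf("BarcodePanel with %d barcodes (RPA %.1f deg):\n",
              length(object@barcodes), object@dispersion@rpaDeg))
  d <- interspotDistance(object)
  for (i in seq_along(d)) cat(sprintf("  %-12s %.2f px\n", names(d)[i], d[i]))
})

setMethod("show", "GroundTruth", function(object) {
  r <- object@records
  cat(sprintf("GroundTruth: %d records in %d FOVs (%d spurious)\n",
              nrow(r), length(unique(r$fov_id)), sum(r$class_label == "spurious")))
  print(table(r$class_label))
})

setMethod("show", "FOVStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("FOVStack: %d FOVs of %d x %d px\n", d[3], d[1], d[2]))
})

setMethod("show", "CropSet", function(object) {
  cat(sprintf("CropSet: %d crops of 24 x 10 px from %d FOVs\n",
              nCrops(object), length(unique(object@info$fov_id))))
})

setMethod("show", "PreparedCrops", function(object) {
  cat(sprintf("PreparedCrops: %d crops (%d rejected)\n",
              nCrops(object), sum(object@rejected)))
})

setMethod("show", "BarcodeClassifier", function(object) {
  cat(sprintf("BarcodeClassifier: %d classes (%s)\n",
              length(object@classes), paste(object@classes, collapse = ", ")))
  if (!is.null(object@validation$accuracy))
    cat(sprintf("  validation accuracy %.3f on %d held-out crops\n",
                object@validation$accuracy, object@validation$n))
})

setMethod("show", "RatioEstimate", function(object) {
  cat("RatioEstimate (composition sums to 1):\n")
  p <- object@composition
  hw <- if (length(object@halfWidths)) object@halfWidths else rep(NA_real_, length(p))
  for (i in seq_along(p))
    cat(sprintf("  %-12s %.4f %s\n", names(p)[i], p[i],
                if (is.na(hw[i])) "" else sprintf("+/- %.4f (95%%)", hw[i])))
})

#' Composition accessor
#'
#' @param x a \code{RatioEstimate}.
#' @return named numeric composition summing to 1.
#' @export
composition <- function(x) {
  stopifnot(is(x, "RatioEstimate"))
  x@composition
}

#' Confidence half-width accessor
#'
#' @param x a \code{RatioEstimate} produced by \code{\link{estimateUncertainty}}.
#' @return named numeric vector of per-class 2-SD half-widths.
#' @export
halfWidths <- function(x) {
  stopifnot(is(x, "RatioEstimate"))
  x@halfWidths
}
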