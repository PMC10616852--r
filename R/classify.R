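# anchor pixel block: 0-based rows 1-2 x cols 4-5 of the 24 x 10 crop,
# the 2x2 block at the crop anchor (the top blob sits at row 2, between
# columns 4 and 5)
.ANCHOR_ROWS <- 2:3
.ANCHOR_COLS <- 5:6

.edgeRing <- function(m) c(m[1, ], m[nrow(m), ], m[2:(nrow(m) - 1), 1],
                           m[2:(nrow(m) - 1), ncol(m)])

#' Symmetrize a 24 x 10 crop to a 120-value half-crop
#'
#' Adds the horizontally flipped mirror image of the crop to itself and keeps
#' only the right half, reducing 240 pixels to 120.  The symmetrized feature
#' is invariant to mirroring.
#'
#' @param m 24 x 10 numeric matrix.
#' @return 24 x 5 matrix (120 values).
#' @export
symmetrizeCrop <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 24L, ncol(m) == 10L)
  s <- m + m[, 10:1]
  s[, 6:10]
}

#' Preprocess crops for classification
#'
#' Per crop: subtract the median of the edge pixels; reject the crop if any
#' of the four central top-blob pixels becomes negative; zero remaining
#' negative pixels; divide by the normalization constant k (the mean of the
#' four anchor pixels, so the normalized anchor mean is exactly 1); and
#' symmetrize to a 120-value half-crop.  k is kept as an extra classification
#' feature.
#'
#' @param crops a \code{\linkS4class{CropSet}}, a 24 x 10 x n array, or a
#'   single 24 x 10 matrix.
#' @param which crop channel when a \code{CropSet} is given (default
#'   denoised, the channel the classifier consumes).
#' @return a \code{\linkS4class{PreparedCrops}}.
#' @export
preprocessCrops <- function(crops, which = "denoised") {
  a <- if (is(crops, "CropSet")) cropArray(crops, which) else
    if (is.matrix(crops)) array(crops, c(dim(crops), 1)) else crops
  stopifnot(length(dim(a)) == 3L, dim(a)[1] == 24L, dim(a)[2] == 10L)
  n <- dim(a)[3]
  halves <- matrix(0, n, 120)
  k <- numeric(n)
  rejected <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    m <- a[, , i]
    m <- m - median(.edgeRing(m))
    anchor <- m[.ANCHOR_ROWS, .ANCHOR_COLS]
    if (any(anchor < 0)) {
      rejected[i] <- TRUE; reason[i] <- "negative anchor"; next
    }
    m[m < 0] <- 0
    ki <- mean(anchor)
    if (ki <= 0) {
      rejected[i] <- TRUE; reason[i] <- "flat crop"; next
    }
    k[i] <- ki
    halves[i, ] <- as.vector(symmetrizeCrop(m / ki))
  }
  new("PreparedCrops", halves = halves, k = k, rejected = rejected,
      reason = reason)
}

#' Augment labeled crops with weak Gaussian noise
#'
#' Each crop contributes itself plus \code{nExtra} noisy copies with labels
#' preserved, so the default triples the training set.  The noise SD is
#' expressed in normalized units (fractions of the crop's anchor-pixel mean
#' after edge-median subtraction), making "weak" scale-free.
#'
#' @param crops 24 x 10 x n array (or \code{CropSet}).
#' @param labels label per crop.
#' @param nExtra noisy copies per crop (default 2).
#' @param noiseSd noise standard deviation in normalized units (default
#'   0.05).
#' @param seed integer seed.
#' @param classesOnly optional label subset to augment (e.g. the miR classes
#'   only); others contribute just themselves.
#' @return list with \code{crops} (24 x 10 x m array), \code{labels} and
#'   \code{origin} (index of the source crop).
#' @export
augmentCrops <- function(crops, labels, nExtra = 2, noiseSd = 0.05, seed = 1,
                         classesOnly = NULL) {
  a <- if (is(crops, "CropSet")) cropArray(crops, "denoised") else crops
  stopifnot(nExtra >= 0, noiseSd >= 0, dim(a)[3] == length(labels))
  set.seed(stageSeed(seed, "augment"))
  n <- dim(a)[3]
  doAug <- if (is.null(classesOnly)) rep(TRUE, n) else labels %in% classesOnly
  copies <- 1L + ifelse(doAug, nExtra, 0L)
  m <- sum(copies)
  out <- array(0, c(24, 10, m))
  outLab <- character(m)
  origin <- integer(m)
  pos <- 0L
  for (i in seq_len(n)) {
    crop <- a[, , i]
    scale <- mean((crop - median(.edgeRing(crop)))[.ANCHOR_ROWS, .ANCHOR_COLS])
    scale <- max(scale, 0)
    for (cpy in seq_len(copies[i])) {
      pos <- pos + 1L
      out[, , pos] <- if (cpy == 1L) crop else
        crop + matrix(rnorm(240, 0, noiseSd * scale), 24, 10)
      outLab[pos] <- labels[i]
      origin[pos] <- i
    }
  }
  list(crops = out, labels = outLab, origin = origin)
}

#' Fit the PCA feature model
#'
#' Principal components of the 120-value half-crops by descending explained
#' variance (default 20 components), plus joint standardization statistics of
#' the 21 features (the 20 PCA coefficients and the normalization constant
#' k) computed on the training set.
#'
#' @param prepared a \code{\linkS4class{PreparedCrops}} (rejected crops are
#'   ignored).
#' @param nComp number of components (default 20).
#' @return a \code{\linkS4class{CropFeatureModel}}.
#' @export
fitFeatureModel <- function(prepared, nComp = 20) {
  stopifnot(is(prepared, "PreparedCrops"))
  X <- prepared@halves[!prepared@rejected, , drop = FALSE]
  kv <- prepared@k[!prepared@rejected]
  if (nrow(X) < nComp)
    stop("need at least ", nComp, " training crops, got ", nrow(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = nComp)
  scores <- pc$x[, seq_len(nComp), drop = FALSE]
  feats <- cbind(scores, k = kv)
  ctr <- colMeans(feats)
  scl <- apply(feats, 2, sd)
  scl[scl == 0] <- 1
  new("CropFeatureModel", rotation = pc$rotation[, seq_len(nComp), drop = FALSE],
      center = pc$center, featCenter = ctr, featScale = scl,
      nComp = as.integer(nComp))
}

#' Standardized classifier features for prepared crops
#'
#' Projects each half-crop on the learnt components and standardizes the 20
#' coefficients together with k to zero mean and unit variance (training-set
#' statistics).
#'
#' @param model a \code{\linkS4class{CropFeatureModel}}.
#' @param prepared a \code{\linkS4class{PreparedCrops}}.
#' @return n x (nComp+1) feature matrix; rejected crops hold NA rows.
#' @export
cropFeatures <- function(model, prepared) {
  stopifnot(is(model, "CropFeatureModel"), is(prepared, "PreparedCrops"))
  S <- sweep(prepared@halves, 2, model@center) %*% model@rotation
  F <- cbind(S, prepared@k)
  F <- sweep(sweep(F, 2, model@featCenter), 2, model@featScale, "/")
  colnames(F) <- c(paste0("PC", seq_len(model@nComp)), "k")
  F[prepared@rejected, ] <- NA_real_
  F
}

#' Train the PCA + RBF-SVM crop classifier
#'
#' Splits the labeled crops 90/10 into training and validation (seeded),
#' augments the training crops with weak Gaussian noise (tripling them by
#' default), fits the PCA feature model on the augmented training set, and
#' trains an RBF-kernel SVM over the 21 standardized features with
#' probability calibration.  The classifier chooses between the target
#' classes and a \code{"noise"} class absorbing bottom-blob crops and false
#' detections.  The held-out validation confusion matrix is stored on the
#' model.
#'
#' @param crops a \code{\linkS4class{CropSet}} or 24 x 10 x n array of
#'   denoised crops.
#' @param labels label per crop (target classes plus \code{"noise"}).
#' @param classes optional class order; defaults to the non-noise labels in
#'   order of appearance, with \code{"noise"} last.  All classes must be
#'   present in \code{labels}.
#' @param nExtra,noiseSd augmentation settings (see
#'   \code{\link{augmentCrops}}).
#' @param augmentMirOnly augment only the target-class crops.
#' @param nComp PCA components (default 20).
#' @param cost SVM cost parameter (default 10).
#' @param gamma RBF kernel width; default 1/(nComp+1), i.e. 1/dim on
#'   unit-variance features.
#' @param valFraction held-out validation fraction (default 0.1).
#' @param seed integer seed (split, augmentation, probability calibration).
#' @return a \code{\linkS4class{BarcodeClassifier}}.
#' @export
trainBarcodeClassifier <- function(crops, labels, classes = NULL, nExtra = 2,
                                   noiseSd = 0.05, augmentMirOnly = FALSE,
                                   nComp = 20, cost = 10, gamma = NULL,
                                   valFraction = 0.1, seed = 1) {
  a <- if (is(crops, "CropSet")) cropArray(crops, "denoised") else crops
  stopifnot(dim(a)[3] == length(labels))
  if (is.null(classes)) {
    classes <- c(setdiff(unique(labels), "noise"), "noise")
  }
  missing <- setdiff(classes, labels)
  if (length(missing))
    stop("class(es) missing from the labeled crops: ",
         paste(missing, collapse = ", "))
  if (is.null(gamma)) gamma <- 1 / (nComp + 1)
  n <- dim(a)[3]
  set.seed(stageSeed(seed, "train-val-split"))
  nVal <- round(valFraction * n)
  valIdx <- sort(sample.int(n, nVal))
  trainIdx <- setdiff(seq_len(n), valIdx)
  aug <- augmentCrops(a[, , trainIdx, drop = FALSE], labels[trainIdx],
                      nExtra = nExtra, noiseSd = noiseSd, seed = seed,
                      classesOnly = if (augmentMirOnly)
                        setdiff(classes, "noise") else NULL)
  prep <- preprocessCrops(aug$crops)
  keep <- !prep@rejected
  fm <- fitFeatureModel(prep, nComp = nComp)
  feats <- cropFeatures(fm, prep)[keep, , drop = FALSE]
  y <- factor(aug$labels[keep], levels = classes)
  set.seed(stageSeed(seed, "svm-probability"))
  model <- e1071::svm(x = feats, y = y, kernel = "radial", cost = cost,
                      gamma = gamma, probability = TRUE, scale = FALSE)
  clf <- new("BarcodeClassifier", svm = model, featureModel = fm,
             classes = classes,
             hyper = list(cost = cost, gamma = gamma, nComp = nComp,
                          nExtra = nExtra, noiseSd = noiseSd,
                          augmentMirOnly = augmentMirOnly,
                          valFraction = valFraction, seed = seed,
                          nTrain = sum(keep), nRejectedTrain = sum(!keep)),
             validation = list())
  if (nVal > 0) {
    valPred <- classifyCrops(clf, a[, , valIdx, drop = FALSE])
    cm <- confusionCounts(labels[valIdx], valPred$class, classes)
    clf@validation <- list(confusion = cm, n = nVal,
                           accuracy = sum(diag(cm)) / max(sum(cm), 1))
  }
  clf
}

#' Classify crops
#'
#' Runs crop preprocessing, feature projection and the SVM.  The predicted
#' class is defined as the argmax of the calibrated probability vector, which
#' guarantees consistency between the label and probability outputs (generic
#' SVM implementations do not).  Crops rejected during preprocessing are
#' assigned to \code{"noise"} by convention and flagged.
#'
#' @param clf a \code{\linkS4class{BarcodeClassifier}}.
#' @param crops a \code{\linkS4class{CropSet}}, 24 x 10 x n array, or an
#'   already-\code{\link{preprocessCrops}}ed \code{PreparedCrops}.
#' @return list with \code{class} (character), \code{prob} (n x nClasses
#'   matrix, rows summing to 1) and \code{rejected} (logical).
#' @export
classifyCrops <- function(clf, crops) {
  stopifnot(is(clf, "BarcodeClassifier"))
  prep <- if (is(crops, "PreparedCrops")) crops else preprocessCrops(crops)
  feats <- cropFeatures(clf@featureModel, prep)
  n <- nrow(feats)
  prob <- matrix(0, n, length(clf@classes),
                 dimnames = list(NULL, clf@classes))
  keep <- which(!prep@rejected)
  if (length(keep)) {
    pr <- predict(clf@svm, feats[keep, , drop = FALSE], probability = TRUE)
    pm <- attr(pr, "probabilities")
    prob[keep, ] <- pm[, clf@classes, drop = FALSE]
  }
  if (any(prep@rejected)) prob[prep@rejected, "noise"] <- 1
  cls <- clf@classes[max.col(prob, ties.method = "first")]
  list(class = cls, prob = prob, rejected = prep@rejected)
}

#' Precision-recall curve by probability thresholding
#'
#' Binary classification for one class by thresholding its predicted
#' probability P_i between 0 and 1; precision and recall are computed at each
#' threshold and the area under the curve is the average precision (step
#' integral over recall).  As the threshold approaches 0 the recall reaches
#' 1.
#'
#' @param prob n x nClasses probability matrix (column names = classes).
#' @param truth true label per row.
#' @param class the class whose probability is thresholded.
#' @param thresholds optional threshold grid; defaults to all distinct
#'   scores.
#' @return list with \code{points} (data.frame threshold/precision/recall)
#'   and \code{auc} (average precision).
#' @export
prCurve <- function(prob, truth, class, thresholds = NULL) {
  stopifnot(is.matrix(prob), class %in% colnames(prob),
            nrow(prob) == length(truth))
  scores <- prob[, class]
  pos <- truth == class
  if (!any(pos)) stop("no positive examples for class '", class, "'")
  if (is.null(thresholds))
    thresholds <- sort(unique(c(scores, 0, 1)), decreasing = TRUE)
  pts <- lapply(thresholds, function(t) {
    sel <- scores >= t
    tp <- sum(sel & pos)
    data.frame(threshold = t,
               precision = if (sum(sel)) tp / sum(sel) else NA_real_,
               recall = tp / sum(pos))
  })
  pts <- do.call(rbind, pts)
  # average precision: sum of precision x recall increments over descending
  # thresholds (step integral)
  ok <- !is.na(pts$precision)
  r <- c(0, pts$recall[ok])
  p <- pts$precision[ok]
  auc <- sum(diff(r) * p)
  list(points = pts, auc = auc)
}

#' Empirical PSF of a labeled crop population
#'
#' Pixel-wise median over many noisy crops of one species — a high-SNR
#' empirical estimate of the dual-spot PSF, useful for reporting and visual
#' comparison with simulated barcodes.
#'
#' @param crops a \code{\linkS4class{CropSet}} or 24 x 10 x n array.
#' @param which channel when a \code{CropSet} is given (default noisy).
#' @param labels optional label vector to subset by \code{class}.
#' @param class optional class to select.
#' @return 24 x 10 median image.
#' @export
medianPsf <- function(crops, which = "noisy", labels = NULL, class = NULL) {
  a <- if (is(crops, "CropSet")) cropArray(crops, which) else crops
  if (!is.null(labels) && !is.null(class))
    a <- a[, , labels == class, drop = FALSE]
  .pixelwiseMedian(a)
}
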