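#' Cross-tabulate true vs predicted labels
#'
#' @param truth,predicted equal-length label vectors over the class set.
#' @param classes class order (rows = true class i, cols = predicted class
#'   j).
#' @return integer confusion matrix C with \code{dimnames = list(true,
#'   predicted)}.
#' @export
confusionCounts <- function(truth, predicted, classes) {
  stopifnot(length(truth) == length(predicted))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  C <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(C), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class recall and precision from a confusion matrix
#'
#' Recall r_i = C_ii / sum_j C_ij (fraction of true occurrences of class i
#' correctly detected); precision p_j = C_jj / sum_i C_ij.  Classes with a
#' zero denominator are flagged NA (undefined), never silently 0.
#'
#' @param C confusion matrix (rows = true, cols = predicted).
#' @return data.frame with columns \code{class, recall, precision}.
#' @export
classMetrics <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  rs <- rowSums(C); cs <- colSums(C)
  data.frame(class = rownames(C),
             recall = ifelse(rs > 0, diag(C) / rs, NA_real_),
             precision = ifelse(cs > 0, diag(C) / cs, NA_real_),
             row.names = NULL)
}

#' Normalized confusion matrix
#'
#' Builds the conditional-probability matrix C-hat used for count correction.
#' The \code{"generative"} convention sets C-hat[i, j] = P(predicted = i |
#' true = j) (columns index true classes and sum to 1), the unique choice
#' under which predicted counts satisfy h = C-hat h' identically for any
#' labeled set.  \code{"column-literal"} keeps the orientation C-hat[i, j] =
#' C[i, j] / sum_k C[k, j] for comparison.
#'
#' @param C confusion matrix (rows = true, cols = predicted).
#' @param convention \code{"generative"} (default) or
#'   \code{"column-literal"}.
#' @return column-stochastic numeric matrix.
#' @export
normalizeConfusion <- function(C, convention = c("generative", "column-literal")) {
  convention <- match.arg(convention)
  if (convention == "generative") {
    rs <- rowSums(C)
    if (any(rs == 0)) stop("confusion matrix has an empty true class")
    t(C / rs)
  } else {
    cs <- colSums(C)
    if (any(cs == 0)) stop("confusion matrix has an empty predicted class")
    sweep(C, 2, cs, "/")
  }
}

#' Correct predicted class counts by inverting the normalized confusion
#' matrix
#'
#' With h the classifier's predicted counts and C-hat the normalized
#' confusion matrix, the true counts h' satisfy h = C-hat h'; the best
#' estimate of the true counts is therefore h' = C-hat^-1 h.  Negative
#' components (possible with a noisy C) are clipped to zero with a warning.
#'
#' @param C confusion matrix of the labeled calibration subset.
#' @param h predicted class counts (same class order as C).
#' @param convention passed to \code{\link{normalizeConfusion}}.
#' @param maxCondition condition-number ceiling above which the matrix is
#'   treated as singular.
#' @return corrected counts h'.
#' @export
unconfuse <- function(C, h, convention = "generative", maxCondition = 1e8) {
  stopifnot(is.matrix(C), length(h) == nrow(C))
  M <- normalizeConfusion(C, convention)
  cond <- kappa(M, exact = TRUE)
  if (!is.finite(cond) || cond > maxCondition)
    stop("normalized confusion matrix is ill-conditioned (condition number ",
         format(cond, digits = 3), ")")
  hp <- solve(M, h)
  if (any(hp < 0)) {
    warning("negative corrected count(s) clipped to zero")
    hp[hp < 0] <- 0
  }
  names(hp) <- rownames(C)
  hp
}

#' Predicted class counts of a classification result
#'
#' @param class character vector of predicted labels.
#' @param classes class order.
#' @return named count vector h.
#' @export
classCounts <- function(class, classes) {
  as.vector(table(factor(class, levels = classes))) |>
    stats::setNames(classes)
}

# isometric embedding of the 3-simplex: vertices of an equilateral triangle
.SIMPLEX_V <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), nrow = 3, byrow = TRUE)

.toSimplexPlane <- function(P) P %*% .SIMPLEX_V

# gradients of the barycentric coordinates w.r.t. plane coordinates, and the
# affine inverse mapping xy -> composition
.simplexAffine <- function() {
  V <- .SIMPLEX_V
  Tm <- rbind(V[2, ] - V[1, ], V[3, ] - V[1, ])   # 2 x 2, rows = edge vectors
  Tinv <- solve(t(Tm))                            # xy -> (p2, p3)
  G <- rbind(-colSums(Tinv), Tinv)                # 3 x 2 gradients of p_i
  list(G = G, v1 = V[1, ])
}

.fromSimplexPlane <- function(xy) {
  af <- .simplexAffine()
  p23 <- af$G[2:3, ] %*% (xy - af$v1)
  c(1 - sum(p23), p23)
}

#' Reference-normalized mixture composition (point estimate)
#'
#' Element-wise division of the corrected mixture counts by the corrected
#' counts of the equidistributed (1:1:1) calibration sample cancels shared
#' per-class capture efficiencies and classifier bias; the noise class is
#' dropped and the remaining entries normalized to sum to 1.
#'
#' @param hMix corrected counts of the unknown mixture.
#' @param hRef corrected counts of the 1:1:1 reference sample.
#' @param noiseClass name of the noise entry to drop (default
#'   \code{"noise"}; use NULL if the vectors carry target classes only).
#' @return a \code{\linkS4class{RatioEstimate}} without uncertainty.
#' @export
ratioEstimate <- function(hMix, hRef, noiseClass = "noise") {
  stopifnot(length(hMix) == length(hRef))
  if (!is.null(names(hMix)) && !is.null(names(hRef)) &&
      !identical(names(hMix), names(hRef)))
    stop("mixture and reference counts must share class order")
  if (!is.null(noiseClass) && !is.null(names(hMix)) &&
      noiseClass %in% names(hMix)) {
    keep <- names(hMix) != noiseClass
    hMix <- hMix[keep]; hRef <- hRef[keep]
  }
  if (any(hRef <= 0)) stop("reference class unobserved (zero corrected count)")
  r <- hMix / hRef
  r[r < 0] <- 0
  new("RatioEstimate", composition = r / sum(r))
}

#' Resampling-based uncertainty of the calibrated composition
#'
#' Repeats the unconfusion/normalization procedure with noise injected into
#' its inputs: each repetition draws a pair of confusion matrices from a
#' multinomial distribution whose mean is C (each true-class row resampled
#' with its own total), perturbs the reference and mixture count vectors with
#' Gaussian noise of SD \code{countCv} times their means, unconfuses each
#' count vector with its own randomized matrix, divides and normalizes.  A
#' 2-D Gaussian is fitted to the ensemble on the simplex plane; the reported
#' composition is the fitted mean and the per-class half-widths are two
#' standard deviations (95%) of the covariance projected onto the
#' single-class directions.
#'
#' @param C confusion matrix of the labeled calibration subset.
#' @param hRef,hMix predicted (uncorrected) class counts of the reference and
#'   mixture data sets.
#' @param nReps ensemble size (default 10000).
#' @param countCv Gaussian count perturbation, SD as a fraction of the mean
#'   (default 0.05).
#' @param seed integer seed.
#' @param noiseClass noise entry dropped before normalization.
#' @param convention passed to \code{\link{unconfuse}}.
#' @param maxRetries redraws allowed for singular randomized matrices.
#' @return a \code{\linkS4class{RatioEstimate}} with per-class 2-SD
#'   half-widths.
#' @export
estimateUncertainty <- function(C, hRef, hMix, nReps = 10000, countCv = 0.05,
                                seed = 1, noiseClass = "noise",
                                convention = "generative", maxRetries = 100) {
  stopifnot(is.matrix(C), nReps >= 100, countCv >= 0)
  classes <- rownames(C)
  targets <- setdiff(classes, noiseClass)
  if (length(targets) != 3L)
    stop("the simplex-plane fit expects exactly 3 target classes")
  set.seed(stageSeed(seed, "uncertainty"))
  rowTot <- rowSums(C)
  rowP <- C / rowTot
  k <- nrow(C)
  drawC <- function() {
    M <- matrix(0L, k, k, dimnames = dimnames(C))
    for (i in seq_len(k)) M[i, ] <- rmultinom(1, rowTot[i], rowP[i, ])
    M
  }
  ens <- matrix(NA_real_, nReps, 3)
  retries <- 0L
  for (r in seq_len(nReps)) {
    comp <- NULL
    for (attempt in seq_len(maxRetries)) {
      comp <- tryCatch({
        Cr <- drawC(); Cm <- drawC()
        hr <- pmax(rnorm(k, hRef, countCv * hRef), 0)
        hm <- pmax(rnorm(k, hMix, countCv * hMix), 0)
        hrp <- suppressWarnings(unconfuse(Cr, hr, convention))
        hmp <- suppressWarnings(unconfuse(Cm, hm, convention))
        composition(ratioEstimate(hmp, hrp, noiseClass))
      }, error = function(e) NULL)
      if (!is.null(comp)) break
      retries <- retries + 1L
    }
    if (is.null(comp)) stop("could not draw a non-singular confusion matrix")
    ens[r, ] <- comp
  }
  xy <- .toSimplexPlane(ens)
  mu <- colMeans(xy)
  Sigma <- stats::cov(xy)
  af <- .simplexAffine()
  sds <- sqrt(rowSums((af$G %*% Sigma) * af$G))
  meanComp <- .fromSimplexPlane(mu)
  meanComp <- pmax(meanComp, 0); meanComp <- meanComp / sum(meanComp)
  names(meanComp) <- targets
  hw <- 2 * sds
  names(hw) <- targets
  out <- new("RatioEstimate", composition = meanComp, halfWidths = hw,
             mean2d = mu, cov2d = Sigma, reps = as.integer(nReps),
             countCv = countCv, seed = as.integer(seed))
  attr(out, "retries") <- retries
  out
}
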