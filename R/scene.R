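#' Sample ground truth for a synthetic scene
#'
#' Draws molecule anchor positions (top-blob centres) by rejection sampling so
#' that every position respects the FOV margin and a minimum pairwise
#' separation, plus a configurable fraction of spurious single-blob
#' distractors.  Brightness multipliers are log-normal.  Deterministic for a
#' fixed seed.
#'
#' @param countsPerClass named integer vector: molecules per class per FOV.
#' @param nFov number of fields of view.
#' @param fovShape c(rows, cols) in pixels (default 256 x 256).
#' @param margin minimum distance from any FOV edge, pixels; must cover the
#'   24 x 10 crop extent around the anchor.
#' @param minSep minimum separation between any two objects in a FOV, pixels.
#' @param spuriousRate spurious blobs as a fraction of the molecule count.
#' @param brightnessMeanLog,brightnessSdLog log-normal brightness parameters.
#' @param spuriousScale brightness scale factor of spurious blobs.
#' @param seed integer seed.
#' @param maxTries rejection-sampling attempts per object before giving up.
#' @return a \code{\linkS4class{GroundTruth}}.
#' @export
sampleGroundTruth <- function(countsPerClass, nFov = 10, fovShape = c(256, 256),
                              margin = 24, minSep = 10, spuriousRate = 0.2,
                              brightnessMeanLog = log(1200),
                              brightnessSdLog = 0.3, spuriousScale = 0.9,
                              seed = 1, maxTries = 500) {
  stopifnot(length(countsPerClass) >= 1, !is.null(names(countsPerClass)),
            all(countsPerClass >= 0), nFov >= 1)
  if (margin < 22) stop("margin must cover the 24 x 10 crop extent (>= 22 px)")
  if (minSep <= 0) stop("minSep must be positive")
  set.seed(stageSeed(seed, "ground-truth"))
  nMol <- sum(countsPerClass)
  nSpur <- round(spuriousRate * nMol)
  classes <- c(rep(names(countsPerClass), times = countsPerClass),
               rep("spurious", nSpur))
  rows <- cols <- numeric(0)
  recs <- vector("list", nFov)
  for (f in seq_len(nFov)) {
    pr <- pc <- numeric(length(classes))
    for (i in seq_along(classes)) {
      ok <- FALSE
      for (t in seq_len(maxTries)) {
        r <- stats::runif(1, margin, fovShape[1] - margin)
        c <- stats::runif(1, margin, fovShape[2] - margin)
        if (i == 1L ||
            min((pr[seq_len(i - 1)] - r)^2 + (pc[seq_len(i - 1)] - c)^2) >= minSep^2) {
          pr[i] <- r; pc[i] <- c; ok <- TRUE; break
        }
      }
      if (!ok) stop("scene too dense: cannot satisfy minSep after ", maxTries,
                    " retries")
    }
    bright <- stats::rlnorm(length(classes), brightnessMeanLog, brightnessSdLog)
    bright[classes == "spurious"] <- bright[classes == "spurious"] * spuriousScale
    recs[[f]] <- data.frame(fov_id = rep(f, length(classes)),
                            class_label = classes, row = pr,
                            col = pc, brightness = bright)
  }
  new("GroundTruth", records = do.call(rbind, recs),
      config = list(countsPerClass = countsPerClass, nFov = nFov,
                    fovShape = fovShape, margin = margin, minSep = minSep,
                    spuriousRate = spuriousRate,
                    brightnessMeanLog = brightnessMeanLog,
                    brightnessSdLog = brightnessSdLog,
                    spuriousScale = spuriousScale, seed = seed))
}

# smooth low-order polynomial background field, shared across FOVs so the
# pixel-wise median subtraction removes it exactly
.backgroundField <- function(fovShape, amp) {
  u <- (seq_len(fovShape[1]) - 1) / (fovShape[1] - 1)
  v <- (seq_len(fovShape[2]) - 1) / (fovShape[2] - 1)
  amp * (0.6 + 0.25 * outer(u, rep(1, length(v))) +
           0.15 * outer(rep(1, length(u)), v) +
           0.30 * outer(u, v) - 0.20 * outer((u - 0.5)^2, rep(1, length(v))))
}

#' Render a synthetic multi-FOV stack from ground truth
#'
#' Adds each molecule's noiseless barcode patch (interpolated from the
#' barcode's fine dispersion-axis profile, anchored on the top blob) at its
#' subpixel position scaled by its brightness; spurious records are rendered
#' as single isotropic Gaussians.  A smooth inhomogeneous background is added
#' identically across FOVs (optionally jittered per FOV), then the simulator
#' noise model is applied per FOV.
#'
#' @param gt a \code{\linkS4class{GroundTruth}}.
#' @param panel a \code{\linkS4class{BarcodePanel}} covering every class in
#'   \code{gt}.
#' @param backgroundAmp amplitude of the background field (0 disables).
#' @param backgroundJitter per-FOV multiplicative jitter SD (0 = identical
#'   background in all FOVs).
#' @param noise logical; apply the Poisson+Gaussian noise model.
#' @param seed integer seed for noise and jitter.
#' @return a \code{\linkS4class{FOVStack}}.
#' @export
renderScene <- function(gt, panel, backgroundAmp = 20, backgroundJitter = 0,
                        noise = TRUE, seed = 1) {
  stopifnot(is(gt, "GroundTruth"), is(panel, "BarcodePanel"))
  cfg <- panel@config
  shape <- gt@config$fovShape
  labs <- classLabels(panel)
  gtClasses <- setdiff(unique(gt@records$class_label), "spurious")
  if (!all(gtClasses %in% labs))
    stop("no barcode for class(es): ",
         paste(setdiff(gtClasses, labs), collapse = ", "))
  profs <- lapply(panel@barcodes, function(b) b@profile)
  names(profs) <- labs
  sigma <- cfg@sigmaPx
  bg <- if (backgroundAmp > 0) .backgroundField(shape, backgroundAmp) else
    matrix(0, shape[1], shape[2])
  nF <- gt@config$nFov
  stack <- array(0, dim = c(shape[1], shape[2], nF))
  set.seed(stageSeed(seed, "background-jitter"))
  jit <- if (backgroundJitter > 0) 1 + rnorm(nF, 0, backgroundJitter) else rep(1, nF)
  for (f in seq_len(nF)) {
    img <- bg * jit[f]
    rf <- gt@records[gt@records$fov_id == f, ]
    for (i in seq_len(nrow(rf))) {
      row <- rf$row[i]; col <- rf$col[i]; b <- rf$brightness[i]
      if (rf$class_label[i] == "spurious") {
        rr <- max(1, floor(row - 6 + 1)):min(shape[1], ceiling(row + 6 + 1))
        cc <- max(1, floor(col - 6 + 1)):min(shape[2], ceiling(col + 6 + 1))
        amp <- b / (2 * pi * sigma^2)
        patch <- amp * outer(exp(-((rr - 1) - row)^2 / (2 * sigma^2)),
                             exp(-((cc - 1) - col)^2 / (2 * sigma^2)))
      } else {
        p <- profs[[rf$class_label[i]]]
        rr <- max(1, floor(row + min(p$grid) + 1)):min(shape[1], ceiling(row + max(p$grid) + 1))
        cc <- max(1, floor(col - 6 + 1)):min(shape[2], ceiling(col + 6 + 1))
        pv <- approx(p$grid, p$value, xout = (rr - 1) - row, rule = 1)$y
        pv[is.na(pv)] <- 0
        patch <- b * outer(pv, .colKernel(cc - 1, col, sigma))
      }
      img[rr, cc] <- img[rr, cc] + patch
    }
    stack[, , f] <- if (noise) addNoise(img, cfg, seed = stageSeed(seed, paste0("noise-fov-", f)))
    else img
  }
  new("FOVStack", images = stack, fovIds = seq_len(nF),
      metadata = list(seed = seed, backgroundAmp = backgroundAmp,
                      backgroundJitter = backgroundJitter, noise = noise,
                      panelClasses = labs))
}

#' Write / read ground truth CSV
#'
#' Columns \code{fov_id,class_label,row,col,brightness}; pixel coordinates
#' are 0-based with row along the dispersion axis.
#'
#' @param gt a \code{\linkS4class{GroundTruth}}.
#' @param path output CSV path.
#' @export
writeGroundTruthCsv <- function(gt, path) {
  write.csv(truthRecords(gt), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruthCsv
#' @param config optional scene configuration list to attach.
#' @export
readGroundTruthCsv <- function(path, config = list()) {
  df <- read.csv(path)
  if (is.null(config$nFov)) config$nFov <- max(df$fov_id)
  new("GroundTruth", records = df, config = config)
}
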