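.PIPELINE_KEYS <- c("panel", "training", "reference", "mixture", "detect",
                    "classify", "calibrate", "scene", "output", "seed")

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by \code{\link{runPipeline}}:
#' panel definition, per-stage parameters and the global seed from which
#' every stochastic stage derives its own seed.  The defaults describe the
#' standard synthetic benchmark: single-species training scenes, a 1:1:1
#' calibration mixture and a 2:5:3 test mixture.
#'
#' @param seed global seed.
#' @return named configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    panel = list(rpaDeg = 177.5),
    scene = list(fovShape = c(256, 256), margin = 24, minSep = 10,
                 spuriousRate = 0.2, backgroundAmp = 20,
                 brightnessMeanLog = log(1200), brightnessSdLog = 0.3),
    training = list(molsPerFov = 150, nFov = 4),
    reference = list(molsPerFov = 150, nFov = 12, nLabel = 4000),
    mixture = list(ratio = c(2, 5, 3), molsPerFov = 150, nFov = 12),
    detect = list(kMad = 5, dMerge = 2),
    classify = list(nComp = 20, cost = 10, nExtra = 2, noiseSd = 0.05,
                    valFraction = 0.1, denoise = "gaussian",
                    denoiseSigma = 0.7),
    calibrate = list(nReps = 10000, countCv = 0.05),
    output = list(writeImages = FALSE),
    seed = seed)
}

#' Validate a pipeline configuration
#'
#' Merges a user configuration over the defaults; unknown keys are rejected
#' with the offending name.
#'
#' @param config partial configuration list (or a YAML file path).
#' @return completed configuration list.
#' @export
validatePipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- defaultPipelineConfig()
  unknown <- setdiff(names(config), .PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(base[[k]]) && is.list(config[[k]])) {
      unknown <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(unknown))
        stop("unknown key(s) in '", k, "': ", paste(unknown, collapse = ", "))
      base[[k]][names(config[[k]])] <- config[[k]]
    } else base[[k]] <- config[[k]]
  }
  if (is.null(base$panel)) stop("configuration is missing the 'panel' block")
  base
}

# generate + preprocess + detect + crop one scene; internal workhorse shared
# by the pipeline stages
.sceneToCrops <- function(countsPerClass, nFov, panel, cfg, seedTag, seed) {
  sc <- cfg$scene
  gt <- sampleGroundTruth(countsPerClass, nFov = nFov,
                          fovShape = sc$fovShape, margin = sc$margin,
                          minSep = sc$minSep, spuriousRate = sc$spuriousRate,
                          brightnessMeanLog = sc$brightnessMeanLog,
                          brightnessSdLog = sc$brightnessSdLog,
                          seed = stageSeed(seed, paste0(seedTag, "-gt")))
  stack <- renderScene(gt, panel, backgroundAmp = sc$backgroundAmp,
                       seed = stageSeed(seed, paste0(seedTag, "-render")))
  prep <- preprocessStack(stack, keepFraction = 0.8,
                          denoise = cfg$classify$denoise,
                          sigma = cfg$classify$denoiseSigma)
  locs <- detectStack(prep$denoised, kMad = cfg$detect$kMad)
  locs <- mergeAndFilter(locs, dMerge = cfg$detect$dMerge,
                         fovShape = sc$fovShape,
                         panelMinDistance = min(interspotDistance(panel)))
  crops <- extractCrops(prep$noisy, prep$denoised, locs)
  labels <- labelCropsFromTruth(crops, gt)
  list(gt = gt, stack = stack, prep = prep, locs = locs, crops = crops,
       labels = labels)
}

#' Run the full synthetic benchmark pipeline
#'
#' Executes generate -> preprocess -> detect -> crop -> label-from-truth ->
#' train -> classify -> calibrate: single-species scenes provide the labeled
#' training crops; a 1:1:1 mixture provides the confusion matrix (from a
#' labeled subset) and the reference counts; the test mixture is classified,
#' both count vectors are corrected by the inverted normalized confusion
#' matrix, divided element-wise and normalized; uncertainty comes from the
#' multinomial/Gaussian resampling procedure.  Artifacts are written to
#' \code{outDir} (CSV/JSON; images optionally); a rerun with the same
#' configuration reproduces the outputs.
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{validatePipelineConfig}}).
#' @param outDir output directory (created if missing); NULL disables
#'   writing.
#' @return invisible list with the classifier, confusion matrix, count
#'   vectors, point estimate and uncertainty estimate.
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  cfg <- validatePipelineConfig(config)
  seed <- cfg$seed
  t0 <- Sys.time()
  log <- list()
  note <- function(stage, ...) {
    msg <- sprintf(...)
    message(sprintf("[%s] %s", stage, msg))
    log[[length(log) + 1]] <<- list(stage = stage, detail = msg,
                                    elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  }
  panel <- defaultPanel(rpaDeg = cfg$panel$rpaDeg)
  classes <- classLabels(panel)
  note("panel", "%d barcodes, interspot distances %s px", length(classes),
       paste(round(interspotDistance(panel), 2), collapse = ", "))

  # single-species training scenes
  trCrops <- list(); trLabels <- list()
  for (cl in classes) {
    counts <- stats::setNames(rep(0, length(classes)), classes)
    counts[cl] <- cfg$training$molsPerFov
    res <- .sceneToCrops(counts, cfg$training$nFov, panel, cfg,
                         paste0("train-", cl), seed)
    trCrops[[cl]] <- cropArray(res$crops, "denoised")
    trLabels[[cl]] <- res$labels
    note("training", "class %s: %d crops (%d labeled %s)", cl,
         length(res$labels), sum(res$labels == cl), cl)
  }
  allCrops <- array(unlist(trCrops), c(24, 10, sum(vapply(trLabels, length, 1L))))
  allLabels <- unlist(trLabels, use.names = FALSE)
  clf <- trainBarcodeClassifier(allCrops, allLabels,
                                classes = c(classes, "noise"),
                                nExtra = cfg$classify$nExtra,
                                noiseSd = cfg$classify$noiseSd,
                                nComp = cfg$classify$nComp,
                                cost = cfg$classify$cost,
                                valFraction = cfg$classify$valFraction,
                                seed = stageSeed(seed, "train"))
  note("train", "validation accuracy %.3f on %d crops",
       clf@validation$accuracy, clf@validation$n)

  # 1:1:1 reference mixture: confusion matrix from a labeled subset,
  # predicted counts from all crops
  counts <- stats::setNames(rep(round(cfg$reference$molsPerFov / length(classes)),
                                length(classes)), classes)
  ref <- .sceneToCrops(counts, cfg$reference$nFov, panel, cfg, "reference", seed)
  refPred <- classifyCrops(clf, ref$crops)
  nLabel <- min(cfg$reference$nLabel, length(ref$labels))
  labIdx <- seq_len(nLabel)
  C <- confusionCounts(ref$labels[labIdx], refPred$class[labIdx],
                       c(classes, "noise"))
  hRef <- classCounts(refPred$class, c(classes, "noise"))
  note("reference", "%d crops (%d labeled for calibration)",
       length(ref$labels), nLabel)

  # test mixture at the configured ratio
  ratio <- cfg$mixture$ratio
  counts <- stats::setNames(round(cfg$mixture$molsPerFov * ratio / sum(ratio)),
                            classes)
  mix <- .sceneToCrops(counts, cfg$mixture$nFov, panel, cfg, "mixture", seed)
  mixPred <- classifyCrops(clf, mix$crops)
  hMix <- classCounts(mixPred$class, c(classes, "noise"))
  note("mixture", "%d crops classified", length(mixPred$class))

  hRefC <- unconfuse(C, hRef)
  hMixC <- unconfuse(C, hMix)
  point <- ratioEstimate(hMixC, hRefC)
  unc <- estimateUncertainty(C, hRef, hMix, nReps = cfg$calibrate$nReps,
                             countCv = cfg$calibrate$countCv,
                             seed = stageSeed(seed, "uncertainty"))
  note("calibrate", "composition %s (+/- %s)",
       paste(round(composition(unc), 3), collapse = ":"),
       paste(round(halfWidths(unc), 3), collapse = ":"))

  out <- list(config = cfg, panel = panel, classifier = clf, confusion = C,
              hRef = hRef, hMix = hMix, hRefCorrected = hRefC,
              hMixCorrected = hMixC, point = point, uncertainty = unc,
              reference = ref, mixture = mix, log = log)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
    manifest <- list(config = cfg,
                     config_hash = sum(utf8ToInt(as.character(cfgJson))),
                     created = format(Sys.time()))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeGroundTruthCsv(ref$gt, file.path(outDir, "reference_truth.csv"))
    writeGroundTruthCsv(mix$gt, file.path(outDir, "mixture_truth.csv"))
    writeLocalizationsCsv(ref$locs, file.path(outDir, "reference_locs.csv"))
    writeLocalizationsCsv(mix$locs, file.path(outDir, "mixture_locs.csv"))
    write.csv(data.frame(crop_id = seq_along(mixPred$class),
                         label = mixPred$class),
              file.path(outDir, "mixture_pred.csv"), row.names = FALSE)
    writeConfusionCsv(C, file.path(outDir, "confusion.csv"))
    write.csv(data.frame(class = names(hRef), h_ref = as.vector(hRef),
                         h_mix = as.vector(hMix),
                         h_ref_corrected = as.vector(hRefC),
                         h_mix_corrected = as.vector(hMixC)),
              file.path(outDir, "counts.csv"), row.names = FALSE)
    writeRatioJson(unc, file.path(outDir, "ratio.json"))
    writeLines(vapply(log, function(l) as.character(jsonlite::toJSON(l, auto_unbox = TRUE)),
                      character(1)),
               file.path(outDir, "log.jsonl"))
    if (isTRUE(cfg$output$writeImages)) {
      writeStackTiff(ref$stack, file.path(outDir, "reference_stack.tiff"))
      writeStackTiff(mix$stack, file.path(outDir, "mixture_stack.tiff"))
    }
  }
  invisible(out)
}
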