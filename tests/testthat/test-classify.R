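# distinct synthetic crop patterns for separable-classifier toys: blob pairs
# at different offsets, far beyond any noise
toyCrop <- function(class, noiseSd = 0.02) {
  offsets <- c(A = 6, B = 12, C = 18)
  m <- cleanTopBlobCrop(amplitude = 10)
  if (class != "noise")
    m <- m + cleanTopBlobCrop(amplitude = 8)[c((24 - offsets[[class]] + 1):24,
                                               1:(24 - offsets[[class]])), ]
  m + matrix(rnorm(240, 0, noiseSd), 24, 10)
}

toySet <- function(nPerClass = 40, classes = c("A", "B", "C", "noise"),
                   seed = 41) {
  set.seed(seed)
  labels <- rep(classes, each = nPerClass)
  a <- array(0, c(24, 10, length(labels)))
  for (i in seq_along(labels)) a[, , i] <- toyCrop(labels[i])
  list(crops = a, labels = labels)
}

test_that("crop preprocessing normalizes the anchor block to mean 1", {
  # clean top blob with the four anchor pixels equal to 4 on zero background
  m <- matrix(0, 24, 10)
  m[2:3, 5:6] <- 4
  prep <- preprocessCrops(m)
  expect_false(prep@rejected)
  expect_equal(prep@k, 4)
  # normalized anchor mean is exactly 1 (here the anchor pixels are all 1)
  norm <- m / prep@k
  expect_equal(mean(norm[2:3, 5:6]), 1)
  # a negative pixel far from the anchor is zeroed, crop retained
  m2 <- m
  m2[20, 2] <- -0.5
  prep2 <- preprocessCrops(m2)
  expect_false(prep2@rejected)
  expect_equal(prep2@k, 4)
  expect_true(all(prep2@halves >= 0))
})

test_that("degenerate crops are rejected with a reason", {
  # uniform crop: edge median removes everything, anchor mean 0
  prep <- preprocessCrops(matrix(7, 24, 10))
  expect_true(prep@rejected)
  expect_match(prep@reason, "flat")
  # negative anchor after edge-median subtraction
  m <- matrix(5, 24, 10)
  m[2, 5] <- 1
  prep2 <- preprocessCrops(m)
  expect_true(prep2@rejected)
  expect_match(prep2@reason, "negative anchor")
})

test_that("preprocessing is scale-invariant with k absorbing the scale", {
  m <- cleanTopBlobCrop(amplitude = 7, background = 0.5)
  p1 <- preprocessCrops(m)
  p2 <- preprocessCrops(m * 3.7)
  expect_equal(p2@k, 3.7 * p1@k)
  expect_equal(p2@halves, p1@halves, tolerance = 1e-12)
})

test_that("symmetrization folds 240 pixels to 120 and matches a brute-force flip-add", {
  # left-right symmetric crop: output is twice its right half
  m <- cleanTopBlobCrop()
  s <- symmetrizeCrop(m)
  expect_equal(dim(s), c(24L, 5L))
  expect_length(as.vector(s), 120)
  expect_equal(s, 2 * m[, 6:10])
  # brute-force oracle on random and on single-pixel crops
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rnorm(240), 24, 10)
    want <- matrix(0, 24, 5)
    for (i in 1:24) for (j in 6:10)
      want[i, j - 5] <- m[i, j] + m[i, 10 - j + 1]
    expect_equal(symmetrizeCrop(m), want)
  }
  one <- matrix(0, 24, 10); one[1, 1] <- 1
  s1 <- symmetrizeCrop(one)
  expect_equal(s1[1, 5], 1)   # mirrored into the outermost right column
  expect_equal(sum(s1), 1)
  # mirror-invariance: symmetrize(mirror(m)) == symmetrize(m)
  m <- matrix(rnorm(240), 24, 10)
  expect_equal(symmetrizeCrop(m[, 10:1]), symmetrizeCrop(m))
})

test_that("augmentation triples the labeled set and preserves labels", {
  set.seed(43)
  a <- array(rnorm(24 * 10 * 100, 5), c(24, 10, 100))
  labels <- sample(c("A", "B", "noise"), 100, TRUE)
  aug <- augmentCrops(a, labels, nExtra = 2, noiseSd = 0.05, seed = 1)
  expect_equal(dim(aug$crops)[3], 300)
  expect_equal(table(aug$labels), table(rep(labels, each = 3)),
               ignore_attr = TRUE)
  # zero noise: copies identical to originals
  aug0 <- augmentCrops(a, labels, nExtra = 2, noiseSd = 0, seed = 1)
  expect_equal(aug0$crops[, , 2], aug0$crops[, , 1])
  # restriction to selected classes leaves others unaugmented
  augM <- augmentCrops(a, labels, nExtra = 2, seed = 1,
                       classesOnly = c("A", "B"))
  expect_equal(dim(augM$crops)[3], 100 + 2 * sum(labels != "noise"))
})

test_that("the feature model yields 21 standardized features from 20 components", {
  ts <- toySet(nPerClass = 30)
  prep <- preprocessCrops(ts$crops)
  fm <- fitFeatureModel(prep, nComp = 20)
  F <- cropFeatures(fm, prep)
  expect_equal(ncol(F), 21)
  kept <- !prep@rejected
  # standardized training features: zero mean, unit variance per dimension
  expect_true(all(abs(colMeans(F[kept, ])) < 1e-9))
  expect_true(all(abs(apply(F[kept, ], 2, var) - 1) < 1e-6))
  # nested-subspace reconstruction: 20 components beat 10
  fm10 <- fitFeatureModel(prep, nComp = 10)
  X <- prep@halves[kept, ]
  recon <- function(fm) {
    S <- sweep(X, 2, fm@center) %*% fm@rotation
    sum((X - (S %*% t(fm@rotation) + rep(fm@center, each = nrow(X))))^2)
  }
  expect_lte(recon(fm), recon(fm10))
  expect_error(fitFeatureModel(preprocessCrops(ts$crops[, , 1:12]), 20),
               "at least 20")
})

test_that("a separable toy set is classified perfectly and deterministically", {
  ts <- toySet(nPerClass = 40)
  clf <- trainBarcodeClassifier(ts$crops, ts$labels, seed = 7)
  expect_equal(clf@validation$accuracy, 1)
  # validation holds out 10% of the labeled crops
  expect_equal(clf@validation$n, round(0.1 * 160))
  # training crops are recovered exactly
  pred <- classifyCrops(clf, ts$crops)
  expect_equal(pred$class, ts$labels)
  # determinism: same seed, same data, same support vectors
  clf2 <- trainBarcodeClassifier(ts$crops, ts$labels, seed = 7)
  expect_identical(clf@svm$tot.nSV, clf2@svm$tot.nSV)
  expect_equal(clf@svm$rho, clf2@svm$rho)
  # a missing class is an error
  expect_error(trainBarcodeClassifier(ts$crops, rep("A", 160),
                                      classes = c("A", "B", "noise")),
               "missing")
})

test_that("probability vectors are calibrated, length 4 and argmax-consistent", {
  ts <- toySet(nPerClass = 40)
  clf <- trainBarcodeClassifier(ts$crops, ts$labels, seed = 7)
  pred <- classifyCrops(clf, ts$crops)
  expect_equal(dim(pred$prob), c(160L, 4L))
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-9))
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
  # predict is defined as the argmax of the probability vector
  expect_equal(pred$class,
               clf@classes[max.col(pred$prob, ties.method = "first")])
  # a rejected (flat) crop is assigned to noise and flagged
  flat <- array(5, c(24, 10, 1))
  pf <- classifyCrops(clf, flat)
  expect_true(pf$rejected)
  expect_equal(pf$class, "noise")
  expect_equal(pf$prob[1, "noise"], 1, ignore_attr = TRUE)
})

test_that("precision-recall curves match a brute-force threshold sweep", {
  # perfect scores: AUC-PR = 1
  prob <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
                 dimnames = list(NULL, c("A", "noise")))
  truth <- c("A", "A", "noise", "noise")
  expect_equal(prCurve(prob, truth, "A")$auc, 1)
  # constant scores on a balanced set: precision equals prevalence
  probC <- matrix(0.5, 10, 2, dimnames = list(NULL, c("A", "noise")))
  truthC <- rep(c("A", "noise"), 5)
  ptsC <- prCurve(probC, truthC, "A")$points
  attained <- ptsC[!is.na(ptsC$precision) & ptsC$recall > 0, ]
  expect_true(all(abs(attained$precision - 0.5) < 1e-12))
  # random scores against an exhaustive confusion-count sweep
  set.seed(44)
  s <- runif(50)
  prob2 <- cbind(A = s, noise = 1 - s)
  truth2 <- sample(c("A", "noise"), 50, TRUE)
  pr <- prCurve(prob2, truth2, "A")
  for (r in sample(nrow(pr$points), 10)) {
    t <- pr$points$threshold[r]
    tp <- sum(s >= t & truth2 == "A")
    fp <- sum(s >= t & truth2 != "A")
    fn <- sum(s < t & truth2 == "A")
    if (tp + fp > 0)
      expect_equal(pr$points$precision[r], tp / (tp + fp))
    expect_equal(pr$points$recall[r], tp / (tp + fn))
  }
  expect_error(prCurve(prob, rep("noise", 4), "A"), "no positive")
  # threshold -> 0 gives recall 1
  expect_equal(pr$points$recall[pr$points$threshold == 0], 1)
})

test_that("the empirical median PSF shows the dual-spot structure", {
  ts <- toySet(nPerClass = 60)
  med <- medianPsf(ts$crops, labels = ts$labels, class = "B")
  expect_equal(dim(med), c(24L, 10L))
  prof <- rowSums(med)
  expect_gt(prof[3], 0.5 * max(prof))       # top blob at row 2 (0-based)
  expect_gt(prof[15], 0.5 * max(prof))      # second blob 12 rows below
})
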