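test_that("confusion counts are an exact cross-tabulation", {
  # hand-counted 2-class example
  C <- confusionCounts(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(C), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  # perfect predictions: diagonal with the class counts
  truth <- rep(c("A", "B", "C"), c(5, 3, 2))
  Cd <- confusionCounts(truth, truth, c("A", "B", "C"))
  expect_equal(unname(diag(Cd)), c(5L, 3L, 2L))
  expect_equal(sum(Cd) - sum(diag(Cd)), 0L)
  # the total equals the number of labels
  set.seed(51)
  t2 <- sample(c("A", "B", "C"), 77, TRUE)
  p2 <- sample(c("A", "B", "C"), 77, TRUE)
  expect_equal(sum(confusionCounts(t2, p2, c("A", "B", "C"))), 77L)
  expect_error(confusionCounts(c("A", "X"), c("A", "A"), c("A", "B")),
               "unknown label")
})

test_that("recall and precision follow their marginal definitions", {
  C <- matrix(c(8, 1, 2, 9), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  m <- classMetrics(C)
  expect_equal(m$recall[1], 0.8)
  expect_equal(m$precision[1], 8 / 9)
  # identity-like matrix: all ones
  Ci <- diag(c(4, 5, 6))
  dimnames(Ci) <- list(c("A", "B", "C"), c("A", "B", "C"))
  mi <- classMetrics(Ci)
  expect_true(all(mi$recall == 1) && all(mi$precision == 1))
  # an empty true class is flagged undefined, not silently zero
  C0 <- matrix(c(0, 0, 3, 10), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_true(is.na(classMetrics(C0)$recall[1]))
})

test_that("unconfusion inverts the generative confusion model exactly", {
  classes <- c("A", "B", "C", "noise")
  # perfect classifier: h unchanged
  Cd <- diag(c(10, 20, 30, 40))
  dimnames(Cd) <- list(classes, classes)
  expect_equal(unconfuse(Cd, c(5, 6, 7, 8)), c(5, 6, 7, 8),
               ignore_attr = TRUE)
  # algebraic identity on any labeled set: correcting the predicted counts
  # (column sums) recovers the true counts (row sums) to machine precision
  set.seed(52)
  for (rep in 1:10) {
    C <- matrix(rpois(16, 30) + diag(4) * 200, 4, 4,
                dimnames = list(classes, classes))
    h <- colSums(C)
    expect_equal(unconfuse(C, h), rowSums(C), tolerance = 1e-12)
    # total count conserved (the normalized matrix is column-stochastic)
    hc <- as.vector(normalizeConfusion(C) %*% c(100, 200, 300, 400))
    expect_equal(sum(unconfuse(C, hc)), sum(hc), tolerance = 1e-9)
  }
  # an all-zero class row makes the matrix singular
  Cz <- Cd; Cz[2, ] <- 0; Cz[, 2] <- 0
  expect_error(unconfuse(Cz, c(1, 1, 1, 1)))
  # negative corrected counts are clipped with a warning
  Cn <- matrix(c(60, 40, 40, 60), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(hn <- unconfuse(Cn, c(100, 0)), "clipped")
  expect_true(all(hn >= 0))
})

test_that("the literal column normalization differs from the generative one", {
  classes <- c("A", "B")
  C <- matrix(c(8, 2, 1, 9), 2, 2, dimnames = list(classes, classes))
  g <- normalizeConfusion(C, "generative")
  l <- normalizeConfusion(C, "column-literal")
  expect_equal(colSums(g), c(A = 1, B = 1))
  expect_equal(colSums(l), c(A = 1, B = 1))
  expect_false(isTRUE(all.equal(g, l)))
  # only the generative convention satisfies h = C-hat h' on labeled data
  expect_equal(as.vector(g %*% rowSums(C)), unname(colSums(C)))
})

test_that("reference normalization cancels shared per-class efficiencies", {
  classes <- c("A", "B", "C", "noise")
  # identical vectors: uniform thirds
  h <- c(A = 10, B = 20, C = 30, noise = 100)
  expect_equal(unname(composition(ratioEstimate(h, h))), rep(1 / 3, 3))
  # capture efficiencies c_i shared by mixture and reference drop out:
  # truth 2:5:3 is recovered exactly
  eff <- c(0.2, 0.9, 0.55)
  hRef <- c(eff * c(1, 1, 1) * 1000, 500)
  hMix <- c(eff * c(2, 5, 3) * 700, 400)
  names(hRef) <- names(hMix) <- classes
  expect_equal(unname(composition(ratioEstimate(hMix, hRef))),
               c(0.2, 0.5, 0.3))
  # scale invariance in either argument
  expect_equal(composition(ratioEstimate(hMix * 13, hRef)),
               composition(ratioEstimate(hMix, hRef * 0.2)))
  hz <- hRef; hz["B"] <- 0
  expect_error(ratioEstimate(hMix, hz), "reference class unobserved")
})

test_that("resampling intervals shrink with information and match the mean", {
  classes <- c("A", "B", "C", "noise")
  C <- matrix(c(800, 10, 5, 60,
                12, 700, 8, 90,
                6, 9, 750, 80,
                40, 50, 45, 2000), 4, 4, byrow = TRUE,
              dimnames = list(classes, classes))
  hRef <- c(A = 3000, B = 3100, C = 2900, noise = 9000)
  hMix <- c(A = 1500, B = 3800, C = 2200, noise = 9000)
  est <- estimateUncertainty(C, hRef, hMix, nReps = 1500, countCv = 0.05,
                             seed = 3)
  # ensemble mean composition agrees with the point estimate within noise
  point <- composition(ratioEstimate(unconfuse(C, hMix), unconfuse(C, hRef)))
  expect_equal(unname(composition(est)), unname(point), tolerance = 0.02)
  # with cv = 0 and counts scaled far up, the intervals collapse
  big <- estimateUncertainty(C * 400, hRef, hMix, nReps = 400, countCv = 0,
                             seed = 4)
  small <- estimateUncertainty(C, hRef, hMix, nReps = 400, countCv = 0,
                               seed = 4)
  expect_lt(max(halfWidths(big)), max(halfWidths(small)))
  expect_lt(max(halfWidths(big)), 0.01)
  # the default ensemble size is the standard 10,000 repetitions
  expect_equal(eval(formals(estimateUncertainty)$nReps), 10000)
  expect_equal(est@reps, 1500L)
})

test_that("the 95% intervals cover the true composition", {
  set.seed(53)
  classes <- c("A", "B", "C", "noise")
  # generative truth: confusion probabilities and expected counts
  Chat <- matrix(c(0.85, 0.02, 0.01, 0.12,
                   0.02, 0.80, 0.02, 0.16,
                   0.01, 0.03, 0.82, 0.14,
                   0.03, 0.04, 0.03, 0.90), 4, 4, byrow = TRUE)
  Chat <- t(Chat)   # columns = true classes
  trueComp <- c(0.2, 0.5, 0.3)
  nLab <- c(900, 950, 880, 2200)
  refTrue <- c(4000, 4100, 3900, 12000)
  mixTrue <- c(sum(refTrue[1:3]) * trueComp / sum(refTrue[1:3] * trueComp) *
                 refTrue[1:3] * trueComp, 11000)
  mixTrue[1:3] <- refTrue[1:3] * trueComp * 2.5
  hit <- 0; trials <- 60
  for (tr in 1:trials) {
    C <- matrix(0L, 4, 4, dimnames = list(classes, classes))
    for (j in 1:4) {
      draw <- rmultinom(1, nLab[j], Chat[, j])
      C[j, ] <- draw   # row j: true class j over predicted classes
    }
    hRef <- rnorm(4, as.vector((Chat %*% refTrue)), 0.05 * (Chat %*% refTrue))
    hMix <- rnorm(4, as.vector((Chat %*% mixTrue)), 0.05 * (Chat %*% mixTrue))
    est <- estimateUncertainty(C, hRef, hMix, nReps = 300, countCv = 0.05,
                               seed = tr)
    p <- composition(est); hw <- halfWidths(est)
    want <- mixTrue[1:3] / refTrue[1:3]
    want <- want / sum(want)
    # per-class 95% intervals: count marginal coverage over classes
    hit <- hit + sum(abs(p - want) <= hw)
  }
  expect_gte(hit / (3 * trials), 0.9)
})
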