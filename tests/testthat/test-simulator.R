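test_that("effective emission is the pointwise spectrum-filter product", {
  dye <- fixtureDye("af488")
  filt <- fixtureFilter()
  # identity filter leaves the emission unchanged
  expect_equal(effectiveEmission(dye, allPassFilter()), dye@emission)
  # all-zero filter blanks it
  zero <- filterCurve(c(400, 850), c(0, 0))
  expect_equal(effectiveEmission(dye, zero), rep(0, length(dye@emission)))
  # brute-force pointwise oracle on a Gaussian emission x rectangular band
  gauss <- fluorophoreSpectrum("g", seq(400, 850), rep(1, 451),
                               exp(-0.5 * ((seq(400, 850) - 560) / 25)^2))
  band <- filterCurve(c(400, 599, 600, 650, 651, 850), c(0, 0, 1, 1, 0, 0))
  got <- effectiveEmission(gauss, band)
  want <- numeric(length(gauss@wavelengths))
  for (i in seq_along(want))
    want[i] <- gauss@emission[i] * band@transmission[i]
  expect_equal(got, want)
  # zero wherever transmission is zero, non-negative everywhere
  expect_true(all(got[band@transmission == 0] == 0))
  expect_true(all(got >= 0))
})

test_that("disjoint emission and filter ranges are an error", {
  red <- fluorophoreSpectrum("r", seq(700, 850), rep(0.5, 151),
                             exp(-0.5 * ((seq(700, 850) - 750) / 15)^2))
  blueBand <- filterCurve(c(400, 449, 450, 500, 501, 850),
                          c(0, 0, 1, 1, 0, 0))
  expect_error(effectiveEmission(red, blueBand), "no spectral overlap")
})

test_that("RPA adjustment scales the curve by sin((180-RPA)/2)", {
  curve <- fixtureDispersion()
  # 180 degrees: prisms cancel, flat curve
  flat <- rpaAdjust(curve, 180)
  expect_equal(flat@displacement, rep(0, length(curve@displacement)))
  # closed-form factor at 60 degrees: sin(60 deg)
  a60 <- rpaAdjust(curve, 60)
  expect_equal(a60@displacement, curve@displacement * sin(60 * pi / 180))
  expect_equal(a60@rpaDeg, 60)
  # the synthetic-target acquisition angle 177.5: factor sin(1.25 deg)
  a <- rpaAdjust(curve, 177.5)
  expect_equal(a@displacement, curve@displacement * sin(1.25 * pi / 180))
  expect_error(rpaAdjust(curve, 0), "rpaDeg")
  expect_error(rpaAdjust(curve, 200), "rpaDeg")
})

test_that("single-fluorophore render is normalized to the excitation efficiency", {
  filt <- fixtureFilter()
  curve <- rpaAdjust(fixtureDispersion(), 177.5)
  cfg <- simulatorConfig(patchShape = c(60, 40))
  img <- renderFluorophore(fixtureDye("af488"), filt, curve, cfg,
                           anchor = c(10, 19.5))
  expect_equal(sum(img), attr(img, "efficiency"), tolerance = 1e-3)
  expect_true(all(img >= 0))
})

test_that("monochromatic emission lands one Gaussian at the dispersed position", {
  # emission only at 520 nm, linear curve d = 0.05 (lambda - 500): the blob
  # sits exactly 1 px below the zero-dispersion anchor
  dye <- monoDye(520)
  img <- renderFluorophore(dye, allPassFilter(), linearCurve(0.05, 500),
                           simulatorConfig(patchShape = c(40, 20)),
                           anchor = c(10, 9.5))
  prof <- rowSums(img)
  i <- which.max(prof)
  den <- prof[i - 1] - 2 * prof[i] + prof[i + 1]
  peak <- (i - 1) + 0.5 * (prof[i - 1] - prof[i + 1]) / den
  expect_equal(peak, 10 + 1.0, tolerance = 0.02)
})

test_that("excitation efficiency multiplies the render", {
  dye <- monoDye(520, exValue = 0.8, exAt = 488)
  img <- renderFluorophore(dye, allPassFilter(), linearCurve(0.05, 500),
                           simulatorConfig(patchShape = c(60, 40)),
                           anchor = c(20, 19.5))
  expect_equal(sum(img), 0.8, tolerance = 1e-3)
  # zero efficiency for all lasers: warning and a zero image
  dark <- monoDye(520, exValue = 0)
  expect_warning(img0 <- renderFluorophore(dark, allPassFilter(),
                                           linearCurve(0.05, 500)),
                 "zero")
  expect_equal(sum(img0), 0)
})

test_that("dual-fluorophore barcodes have closed-form interspot distances", {
  cfg <- simulatorConfig(patchShape = c(40, 10))
  curve <- linearCurve(0.05, 500)
  # identical dyes collapse to a single blob
  same <- renderPair("same", monoDye(520), monoDye(520), allPassFilter(),
                     curve, cfg)
  expect_equal(interspotDistance(same), 0)
  # 520 and 670 nm at 0.05 px/nm: distance = 0.05 * 150 = 7.5 px
  bc <- renderPair("x", monoDye(520), monoDye(670), allPassFilter(), curve, cfg)
  expect_equal(interspotDistance(bc), 7.5, tolerance = 0.05)
  # the pair image total is the sum of the two efficiencies (up to the tail
  # truncated above the anchored top blob)
  expect_equal(sum(renderPair("y", monoDye(520, 0.7), monoDye(670, 0.5),
                              allPassFilter(), curve,
                              simulatorConfig(patchShape = c(60, 40)))@psf),
               1.2, tolerance = 0.01)
})

test_that("rendered distances match the dispersion-curve difference and RPA 180 collapses them", {
  curve <- fixtureDispersion()
  adj <- rpaAdjust(curve, 177.5)
  for (wl in list(c(440, 521), c(440, 607), c(521, 694))) {
    bc <- renderPair("t", monoDye(wl[1]), monoDye(wl[2]), allPassFilter(),
                     adj, simulatorConfig(patchShape = c(40, 10)))
    want <- adj@displacement[adj@wavelengths == wl[2]] -
      adj@displacement[adj@wavelengths == wl[1]]
    expect_equal(interspotDistance(bc), want, tolerance = 0.05)
  }
  # at RPA 180 every barcode collapses to distance 0
  flat <- rpaAdjust(curve, 180)
  bc <- renderPair("flat", monoDye(440), monoDye(694), allPassFilter(), flat,
                   simulatorConfig(patchShape = c(40, 10)))
  expect_equal(interspotDistance(bc), 0)
})

test_that("interspot distance is invariant under common intensity scaling", {
  cfg <- simulatorConfig(patchShape = c(40, 10))
  curve <- linearCurve(0.05, 500)
  base <- renderPair("b", monoDye(520, 1), monoDye(670, 1), allPassFilter(),
                     curve, cfg)
  scaled <- renderPair("s", monoDye(520, 0.3), monoDye(670, 0.3),
                       allPassFilter(), curve, cfg)
  expect_equal(interspotDistance(base), interspotDistance(scaled))
})

test_that("noiseless render is linear in emission amplitude", {
  dye1 <- monoDye(520)
  dye2 <- dye1
  dye2@emission <- dye2@emission * 3  # same shape, larger amplitude
  cfg <- simulatorConfig(patchShape = c(40, 20))
  a <- renderFluorophore(dye1, allPassFilter(), linearCurve(), cfg)
  b <- renderFluorophore(dye2, allPassFilter(), linearCurve(), cfg)
  # normalization makes amplitude scaling drop out; linearity shows up as an
  # identical normalized image
  expect_equal(unclass(a), unclass(b), ignore_attr = TRUE)
})

test_that("noise model has the configured mean and variance", {
  img <- matrix(0, 400, 300)
  cfg <- simulatorConfig(noiseGaussianMean = 0.3, noiseGaussianVar = 4,
                         poissonScale = 0)
  # degenerate noise: poisson off, zero variance gives input + 0.3 exactly
  cfg0 <- simulatorConfig(noiseGaussianVar = 0, poissonScale = 0)
  expect_equal(addNoise(img, cfg0, seed = 1), img + 0.3)
  # empirical mean of the added noise over 1.2e5 background pixels
  noisy <- addNoise(img, cfg, seed = 7)
  se <- sqrt(4 / length(img))
  expect_lt(abs(mean(noisy) - 0.3), 3 * se)
  # empirical variance of the Gaussian component within 5%
  expect_lt(abs(var(as.vector(noisy)) - 4) / 4, 0.05)
  # deterministic for a fixed seed
  expect_identical(addNoise(img, cfg, seed = 5), addNoise(img, cfg, seed = 5))
  expect_error(addNoise(img - 1, cfg), "non-negative")
})

test_that("panel distinctness flags close interspot distances", {
  mkbc <- function(lab, d) new("SpectralBarcode", classLabel = lab,
                               dyeA = monoDye(500), dyeB = monoDye(600),
                               psf = matrix(0, 24, 10),
                               interspotDistance = d, profile = list(),
                               efficiency = 1)
  # duplicate distance: gap 0, flagged
  dup <- panelDistinctness(list(mkbc("a", 5), mkbc("b", 5)), minGap = 2)
  expect_equal(dup$gap_px, 0)
  expect_true(dup$flagged)
  # distances 3, 6, 9 with min gap 2: no flags
  tbl <- panelDistinctness(list(mkbc("a", 3), mkbc("b", 6), mkbc("c", 9)),
                           minGap = 2)
  expect_false(any(tbl$flagged))
  # gaps equal a brute-force double loop
  panel <- testPanel()
  d <- interspotDistance(panel)
  tbl <- panelDistinctness(panel)
  for (r in seq_len(nrow(tbl)))
    expect_equal(tbl$gap_px[r], abs(d[tbl$class_a[r]] - d[tbl$class_b[r]]),
                 ignore_attr = TRUE)
  expect_error(panelDistinctness(list(mkbc("a", 3))), "at least two")
})
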