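# Shared fixtures, built lazily and cached for the whole test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

testPanel <- function() cached("panel", function() defaultPanel())

# a dye emitting in a single 1 nm bin, for closed-form dispersion checks
monoDye <- function(peakNm, exValue = 1, exAt = 488) {
  wl <- seq(400, 850, by = 1)
  em <- numeric(length(wl)); em[wl == peakNm] <- 1
  ex <- numeric(length(wl)); ex[wl == exAt] <- exValue
  new("FluorophoreSpectrum", name = paste0("mono", peakNm), wavelengths = wl,
      excitation = ex, emission = em)
}

allPassFilter <- function() filterCurve(c(400, 850), c(1, 1))

# linear dispersion d(lambda) = slope * (lambda - ref), already "adjusted"
linearCurve <- function(slope = 0.05, ref = 500, rpaDeg = 90) {
  wl <- seq(400, 850, by = 1)
  new("DispersionCurve", wavelengths = wl, displacement = slope * (wl - ref),
      rpaDeg = rpaDeg)
}

# a clean synthetic 24 x 10 crop: single Gaussian top blob on a constant
# background, anchor-aligned (blob centre row 2, col 4.5, 0-based)
cleanTopBlobCrop <- function(amplitude = 10, background = 0, sigma = 1.15) {
  r <- matrix(0:23, 24, 10)
  c <- matrix(0:9, 24, 10, byrow = TRUE)
  amplitude * exp(-((r - 2)^2 + (c - 4.5)^2) / (2 * sigma^2)) + background
}

# the standard synthetic benchmark shared by the acceptance tests: one
# trained classifier plus a 1:1:1 reference and a 2:5:3 test mixture.
# Sizes follow the benchmark design: ~1500 labeled crops per class for
# training, ~5000 molecules per mixture.
acceptanceBench <- function() cached("bench", function() {
  panel <- testPanel()
  cfg <- defaultPipelineConfig(seed = 20260919)
  cfg$training <- list(molsPerFov = 150, nFov = 14)
  cfg$reference <- list(molsPerFov = 150, nFov = 42, nLabel = 4000)
  cfg$mixture <- list(ratio = c(2, 5, 3), molsPerFov = 150, nFov = 42)
  cfg$calibrate <- list(nReps = 10000, countCv = 0.05)
  runPipeline(cfg)
})
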