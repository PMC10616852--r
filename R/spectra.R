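#' Construct a FluorophoreSpectrum
#'
#' Input curves are linearly interpolated onto the internal 1 nm grid
#' (400-850 nm); values outside the supplied range are zero.
#'
#' @param name dye label.
#' @param wavelengths wavelength grid of the supplied curves, nm.
#' @param excitation excitation fractions in [0, 1].
#' @param emission emission intensities, >= 0.
#' @return a \code{\linkS4class{FluorophoreSpectrum}}.
#' @export
fluorophoreSpectrum <- function(name, wavelengths, excitation, emission) {
  ex <- approx(wavelengths, excitation, xout = .WL_GRID, rule = 1)$y
  em <- approx(wavelengths, emission, xout = .WL_GRID, rule = 1)$y
  ex[is.na(ex)] <- 0
  em[is.na(em)] <- 0
  new("FluorophoreSpectrum", name = name, wavelengths = .WL_GRID,
      excitation = pmin(pmax(ex, 0), 1), emission = pmax(em, 0))
}

#' Construct a FilterCurve
#'
#' @param wavelengths wavelength grid, nm.
#' @param transmission transmission fractions in [0, 1].
#' @return a \code{\linkS4class{FilterCurve}} on the internal 1 nm grid.
#' @export
filterCurve <- function(wavelengths, transmission) {
  tr <- approx(wavelengths, transmission, xout = .WL_GRID, rule = 1)$y
  tr[is.na(tr)] <- 0
  new("FilterCurve", wavelengths = .WL_GRID,
      transmission = pmin(pmax(tr, 0), 1))
}

#' Construct a DispersionCurve
#'
#' @param wavelengths wavelength grid, nm.
#' @param displacement pixel displacement per wavelength (non-decreasing).
#' @param rpaDeg relative prism angle already applied, or NA for a reference
#'   curve.
#' @return a \code{\linkS4class{DispersionCurve}} on the internal 1 nm grid.
#' @export
dispersionCurve <- function(wavelengths, displacement, rpaDeg = NA_real_) {
  d <- approx(wavelengths, displacement, xout = .WL_GRID, rule = 2)$y
  new("DispersionCurve", wavelengths = .WL_GRID, displacement = d,
      rpaDeg = rpaDeg)
}

#' Construct a SimulatorConfig
#'
#' Defaults follow the acquisition model: per-wavelength Gaussians of 1.15 px
#' standard deviation, additive Gaussian noise with mean 0.3, and unit-gain
#' Poisson shot noise.
#'
#' @param sigmaPx Gaussian standard deviation per wavelength, pixels.
#' @param laserLines excitation laser wavelengths, nm.
#' @param patchShape integer c(rows, cols) of rendered patches.
#' @param noiseGaussianMean additive Gaussian mean.
#' @param noiseGaussianVar additive Gaussian variance.
#' @param poissonScale photons per intensity unit (0 disables shot noise).
#' @return a \code{\linkS4class{SimulatorConfig}}.
#' @export
simulatorConfig <- function(sigmaPx = 1.15,
                            laserLines = c(405, 488, 561, 638),
                            patchShape = c(24L, 10L),
                            noiseGaussianMean = 0.3,
                            noiseGaussianVar = 25,
                            poissonScale = 1) {
  new("SimulatorConfig", sigmaPx = sigmaPx, laserLines = laserLines,
      patchShape = as.integer(patchShape),
      noiseGaussianMean = noiseGaussianMean,
      noiseGaussianVar = noiseGaussianVar, poissonScale = poissonScale)
}

# skew-Gaussian shape: widths differ left and right of the peak
.skewGauss <- function(wl, peak, wLeft, wRight) {
  w <- ifelse(wl < peak, wLeft, wRight)
  exp(-0.5 * ((wl - peak) / w)^2)
}

# Parametric stand-ins for four commercial dye classes.  These are synthetic
# shapes (peak positions and widths chosen to resemble the AF405/488/568/647
# families), not measured vendor spectra; real spectra can be loaded from CSV
# with readSpectrumCsv().
.FIXTURE_DYES <- list(
  af405 = list(exPeak = 401, exL = 25, exR = 18, emPeak = 421, emL = 14, emR = 30),
  af488 = list(exPeak = 490, exL = 28, exR = 16, emPeak = 525, emL = 14, emR = 28),
  af568 = list(exPeak = 578, exL = 30, exR = 16, emPeak = 603, emL = 16, emR = 30),
  af647 = list(exPeak = 650, exL = 30, exR = 16, emPeak = 668, emL = 16, emR = 30))

#' Built-in parametric dye spectra
#'
#' Returns a synthetic skew-Gaussian excitation/emission pair approximating a
#' commercial dye class.  Available names: \code{"af405"}, \code{"af488"},
#' \code{"af568"}, \code{"af647"}.
#'
#' @param name fixture dye name.
#' @return a \code{\linkS4class{FluorophoreSpectrum}}.
#' @export
fixtureDye <- function(name) {
  p <- .FIXTURE_DYES[[name]]
  if (is.null(p))
    stop("unknown fixture dye '", name, "'; available: ",
         paste(names(.FIXTURE_DYES), collapse = ", "))
  fluorophoreSpectrum(name, .WL_GRID,
                      .skewGauss(.WL_GRID, p$exPeak, p$exL, p$exR),
                      .skewGauss(.WL_GRID, p$emPeak, p$emL, p$emR))
}

#' Built-in multiband emission filter
#'
#' A five-band notch-style transmission fixture with pass bands centred at
#' 440, 521, 607, 694 and 809 nm (half-width 12.5 nm, peak transmission 0.95,
#' soft logistic edges), mimicking a multiband single-molecule emission
#' filter.
#'
#' @return a \code{\linkS4class{FilterCurve}}.
#' @export
fixtureFilter <- function() {
  centers <- c(440, 521, 607, 694, 809)
  hw <- 12.5
  edge <- 1.5
  tr <- rep(0, length(.WL_GRID))
  for (c0 in centers) {
    band <- 1 / (1 + exp(-((.WL_GRID - (c0 - hw)) / edge))) *
      1 / (1 + exp(((.WL_GRID - (c0 + hw)) / edge)))
    tr <- pmax(tr, 0.95 * band)
  }
  filterCurve(.WL_GRID, tr)
}

#' Built-in dispersion calibration fixture
#'
#' A monotone cubic wavelength-to-pixel displacement curve at the reference
#' prism angle, shaped like prism dispersion (steeper at short wavelengths,
#' displacement ~ 1/lambda^2).  After adjustment to a relative prism angle of
#' 177.5 degrees it spans about 24 px over 400-850 nm, placing the default
#' panel's interspot distances well inside a 24-row crop.  Replaceable via
#' \code{\link{readDispersionCsv}}.
#'
#' @param spanPx displacement span in pixels across 400-850 nm at the
#'   reference angle.
#' @return an unadjusted \code{\linkS4class{DispersionCurve}}.
#' @export
fixtureDispersion <- function(spanPx = 1100) {
  f <- (1 / 400^2 - 1 / .WL_GRID^2) / (1 / 400^2 - 1 / 850^2)
  knots <- seq(1, length(.WL_GRID), length.out = 12)
  sf <- splinefun(.WL_GRID[knots], (spanPx * f)[knots], method = "hyman")
  dispersionCurve(.WL_GRID, sf(.WL_GRID))
}

#' Read a wavelength-indexed curve from CSV
#'
#' Expects a header and two columns, \code{wavelength_nm} and \code{value};
#' the curve is linearly interpolated onto the internal 1 nm grid.
#'
#' @param path CSV file path.
#' @return data.frame with wavelength_nm and value.
#' @keywords internal
.readCurveCsv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("curve CSV must have columns 'wavelength_nm' and 'value': ", path)
  df
}

#' Read a fluorophore spectrum from CSV files
#'
#' @param name dye label.
#' @param excitationPath,emissionPath CSVs with columns
#'   \code{wavelength_nm,value}.
#' @return a \code{\linkS4class{FluorophoreSpectrum}}.
#' @export
readSpectrumCsv <- function(name, excitationPath, emissionPath) {
  ex <- .readCurveCsv(excitationPath)
  em <- .readCurveCsv(emissionPath)
  exi <- approx(ex$wavelength_nm, ex$value, xout = .WL_GRID, rule = 1)$y
  emi <- approx(em$wavelength_nm, em$value, xout = .WL_GRID, rule = 1)$y
  exi[is.na(exi)] <- 0; emi[is.na(emi)] <- 0
  new("FluorophoreSpectrum", name = name, wavelengths = .WL_GRID,
      excitation = pmin(pmax(exi, 0), 1), emission = pmax(emi, 0))
}

#' Read a filter transmission curve from CSV
#'
#' @param path CSV with columns \code{wavelength_nm,value}.
#' @return a \code{\linkS4class{FilterCurve}}.
#' @export
readFilterCsv <- function(path) {
  df <- .readCurveCsv(path)
  filterCurve(df$wavelength_nm, df$value)
}

#' Read a dispersion calibration curve from CSV
#'
#' @param path CSV with columns \code{wavelength_nm,value} (displacement in
#'   pixels at the reference prism angle).
#' @return an unadjusted \code{\linkS4class{DispersionCurve}}.
#' @export
readDispersionCsv <- function(path) {
  df <- .readCurveCsv(path)
  dispersionCurve(df$wavelength_nm, df$value)
}
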