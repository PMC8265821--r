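#' Tabulated spectral curve
#'
#' A `spectral_curve` is a tabulated function of wavelength: radiance
#' (W m-2 sr-1 nm-1), filter transmission or reflection (unitless, in
#' \[0, 1\]), quantum efficiency (unitless), emission spectral density
#' (nm-1), or photon spectral irradiance (photons s-1 m-2 nm-1).
#' Outside its tabulated support a curve is taken to be zero.
#'
#' @param wavelength numeric vector of wavelengths in nm, strictly increasing.
#' @param value numeric vector of the same length, finite and non-negative.
#' @param unit optional character tag describing the value unit (metadata only).
#' @return An object of class `spectral_curve`: a list with elements
#'   `wavelength`, `value` and `unit`.
#' @examples
#' qe <- spectral_curve(c(450, 650), c(0.6, 0.6), unit = "QE")
#' sc_value(qe, 530)
#' @export
spectral_curve <- function(wavelength, value, unit = "") {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have the same length")
  if (length(wavelength) < 1L)
    stop("a spectral_curve needs at least one point")
  if (any(!is.finite(wavelength)) || any(!is.finite(value)))
    stop("wavelengths and values must be finite")
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (any(value < 0))
    stop("spectral values must be non-negative")
  structure(list(wavelength = wavelength, value = value, unit = unit),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve%s: %d points, %g-%g nm, values %g-%g>\n",
              if (nzchar(x$unit)) paste0(" [", x$unit, "]") else "",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value)))
  invisible(x)
}

#' Evaluate a spectral curve at given wavelengths
#'
#' Linear interpolation on the tabulated grid; zero outside the support.
#'
#' @param curve a [spectral_curve()].
#' @param wavelength wavelengths (nm) at which to evaluate.
#' @return numeric vector of interpolated values.
#' @export
sc_value <- function(curve, wavelength) {
  stopifnot(inherits(curve, "spectral_curve"))
  if (length(curve$wavelength) == 1L)
    return(ifelse(wavelength == curve$wavelength, curve$value, 0))
  out <- approx(curve$wavelength, curve$value, xout = wavelength,
                method = "linear", yleft = 0, yright = 0)$y
  out
}

#' Common wavelength grid of several curves
#'
#' The 1-nm grid spanning the intersection of the curves' supports.
#' @param ... spectral curves.
#' @param step grid step in nm (default 1).
#' @return numeric vector of wavelengths; error if the supports are disjoint.
#' @export
sc_common_grid <- function(..., step = 1) {
  curves <- list(...)
  lo <- max(vapply(curves, function(s) min(s$wavelength), 0))
  hi <- min(vapply(curves, function(s) max(s$wavelength), 0))
  if (lo > hi) stop("spectral curves have disjoint wavelength supports")
  seq(lo, hi, by = step)
}

#' Pointwise product of spectral curves on a common 1-nm grid
#'
#' @param ... spectral curves.
#' @param unit unit tag for the result.
#' @return a [spectral_curve()] on the common grid.
#' @export
sc_product <- function(..., unit = "") {
  curves <- list(...)
  grid <- do.call(sc_common_grid, curves)
  v <- rep(1, length(grid))
  for (s in curves) v <- v * sc_value(s, grid)
  spectral_curve(grid, v, unit = unit)
}

#' Integrate a spectral curve over wavelength (trapezoid rule)
#'
#' @param curve a [spectral_curve()].
#' @param step integration grid step in nm (default 1).
#' @return the integral of the curve over its support.
#' @export
sc_integral <- function(curve, step = 1) {
  stopifnot(inherits(curve, "spectral_curve"))
  if (length(curve$wavelength) == 1L) return(0)
  grid <- seq(min(curve$wavelength), max(curve$wavelength), by = step)
  if (length(grid) < 2L) grid <- range(curve$wavelength)
  v <- sc_value(curve, grid)
  sum(diff(grid) * (v[-length(v)] + v[-1]) / 2)
}

#' Scale a spectral curve by a constant
#' @param curve a [spectral_curve()].
#' @param factor non-negative scalar.
#' @param unit unit tag for the result.
#' @return a scaled [spectral_curve()].
#' @export
sc_scale <- function(curve, factor, unit = curve$unit) {
  stopifnot(factor >= 0)
  spectral_curve(curve$wavelength, curve$value * factor, unit = unit)
}

#' Gaussian LED radiance spectrum
#'
#' Default model for the blue LED source: a Gaussian radiance spectrum.
#' Manufacturer tabulations can be substituted via [read_spectrum_csv()].
#'
#' @param center peak wavelength in nm (default 470, blue LED).
#' @param fwhm full width at half maximum in nm (default 25).
#' @param peak_radiance peak spectral radiance in W m-2 sr-1 nm-1.
#' @param range wavelength range covered, nm.
#' @param step tabulation step, nm.
#' @return a [spectral_curve()] of radiance.
#' @export
led_spectrum <- function(center = 470, fwhm = 25, peak_radiance = 1000,
                         range = c(400, 700), step = 1) {
  grid <- seq(range[1], range[2], by = step)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  spectral_curve(grid, peak_radiance * exp(-((grid - center)^2) / (2 * sigma^2)),
                 unit = "W m-2 sr-1 nm-1")
}

#' Top-hat filter transmission (or reflection) spectrum
#'
#' Ideal interference-filter model: unit transmission inside the passband,
#' a small flat out-of-band floor outside it (the measured blocking of the
#' filter cube is about ten orders of magnitude).
#'
#' @param band two-element numeric, passband edges in nm.
#' @param out_of_band flat transmission outside the band (default 1e-10).
#' @param in_band transmission inside the band (default 1).
#' @param range wavelength range covered, nm.
#' @param step tabulation step, nm.
#' @return a [spectral_curve()] of transmission.
#' @export
tophat_filter <- function(band, out_of_band = 1e-10, in_band = 1,
                          range = c(350, 750), step = 1) {
  stopifnot(length(band) == 2L, band[1] < band[2],
            out_of_band >= 0, out_of_band < 1, in_band <= 1)
  grid <- seq(range[1], range[2], by = step)
  v <- ifelse(grid >= band[1] & grid <= band[2], in_band, out_of_band)
  spectral_curve(grid, v, unit = "transmission")
}

#' Flat camera quantum-efficiency spectrum
#'
#' @param qe quantum efficiency value (default 0.6).
#' @param range wavelength range with this QE, nm (default 450-650).
#' @param step tabulation step, nm.
#' @return a [spectral_curve()] of QE.
#' @export
flat_qe <- function(qe = 0.6, range = c(450, 650), step = 1) {
  stopifnot(qe >= 0, qe <= 1)
  grid <- seq(range[1], range[2], by = step)
  spectral_curve(grid, rep(qe, length(grid)), unit = "QE")
}

#' Model emission spectrum of the AF488 fluorophore
#'
#' Skewed Gaussian peaked at 520 nm, normalized to unit area so that the
#' curve is a spectral probability density (nm-1) for emitted photons.
#'
#' @param peak peak emission wavelength in nm (default 520).
#' @param sigma width parameter in nm (default 16).
#' @param skew skewness of the red tail (default 2; > 1 broadens the red side).
#' @param range wavelength range covered, nm.
#' @param step tabulation step, nm.
#' @return a unit-area [spectral_curve()] (nm-1).
#' @export
af488_emission <- function(peak = 520, sigma = 16, skew = 2,
                           range = c(470, 700), step = 1) {
  grid <- seq(range[1], range[2], by = step)
  s <- ifelse(grid < peak, sigma, sigma * skew)
  v <- exp(-((grid - peak)^2) / (2 * s^2))
  area <- sum(diff(grid) * (v[-length(v)] + v[-1]) / 2)
  spectral_curve(grid, v / area, unit = "nm-1")
}

#' Read a spectrum from a two-column CSV
#'
#' Expects columns `wavelength_nm` and `value` (header required).
#'
#' @param path path to the CSV file.
#' @param unit unit tag for the result.
#' @return a [spectral_curve()].
#' @export
read_spectrum_csv <- function(path, unit = "") {
  d <- read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("spectrum CSV must have columns 'wavelength_nm' and 'value'")
  o <- order(d$wavelength_nm)
  spectral_curve(d$wavelength_nm[o], d$value[o], unit = unit)
}
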