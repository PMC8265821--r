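#' Optical setup of the epifluorescence microscope
#'
#' Defaults describe the system used throughout: a 60x NA-1.45 oil/TIRF-class
#' objective on an inverted microscope, blue excitation (465-495 nm) and green
#' emission (515-555 nm) passbands of the filter cube, sample mounted in glass
#' medium of refractive index 1.56, CCD camera with 6.45-um pixels, 5-s
#' exposures.
#'
#' @param na numerical aperture of the objective (unitless).
#' @param n_medium refractive index of the medium holding the sample.
#' @param magnification objective magnification (unitless).
#' @param camera_pixel_pitch camera pixel pitch in um.
#' @param exposure exposure time in s.
#' @param excitation_band two-element nm interval of the excitation passband.
#' @param emission_band two-element nm interval of the emission passband.
#' @param out_of_band_transmission flat blocked-side transmission of each
#'   filter element (default 1e-10, i.e. ten orders of magnitude of blocking).
#' @return an object of class `optical_setup`.
#' @export
optical_setup <- function(na = 1.45, n_medium = 1.56, magnification = 60,
                          camera_pixel_pitch = 6.45, exposure = 5,
                          excitation_band = c(465, 495),
                          emission_band = c(515, 555),
                          out_of_band_transmission = 1e-10) {
  stopifnot(na > 0, na <= n_medium, magnification > 0,
            camera_pixel_pitch > 0, exposure > 0,
            length(excitation_band) == 2L, length(emission_band) == 2L,
            out_of_band_transmission >= 0, out_of_band_transmission < 1)
  if (max(excitation_band) > min(emission_band) &&
      max(emission_band) > min(excitation_band))
    stop("excitation and emission bands must not overlap")
  structure(list(na = na, n_medium = n_medium, magnification = magnification,
                 camera_pixel_pitch = camera_pixel_pitch, exposure = exposure,
                 excitation_band = excitation_band,
                 emission_band = emission_band,
                 out_of_band_transmission = out_of_band_transmission),
            class = "optical_setup")
}

#' Fluorophore photophysics model
#'
#' Defaults are documented typical values for AF488: quantum yield 0.92,
#' fluorescence lifetime 4.1 ns, absorption cross-section 1.212e-20 m2,
#' scattering cross-section 1.1e-13 m2.
#'
#' @param absorption_cross_section m2.
#' @param scattering_cross_section m2 (drives excitation-light leakage).
#' @param quantum_yield unitless in (0, 1].
#' @param lifetime fluorescence lifetime in s.
#' @param emission_spectrum unit-area [spectral_curve()] of emission (nm-1).
#' @param emission_peak peak emission wavelength in nm.
#' @return an object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(absorption_cross_section = 1.212e-20,
                              scattering_cross_section = 1.1e-13,
                              quantum_yield = 0.92, lifetime = 4.1e-9,
                              emission_spectrum = af488_emission(),
                              emission_peak = 520) {
  stopifnot(absorption_cross_section > 0, scattering_cross_section > 0,
            quantum_yield > 0, quantum_yield <= 1, lifetime > 0,
            inherits(emission_spectrum, "spectral_curve"))
  structure(list(absorption_cross_section = absorption_cross_section,
                 scattering_cross_section = scattering_cross_section,
                 quantum_yield = quantum_yield, lifetime = lifetime,
                 emission_spectrum = emission_spectrum,
                 emission_peak = emission_peak),
            class = "fluorophore_model")
}

#' Camera model
#'
#' Defaults describe a cooled interline CCD (1392 x 1040 array, 6.45-um
#' pixels): flat QE 0.6 over 450-650 nm, read noise 6 electrons RMS, dark
#' current 0.05 electrons/pixel/s.
#'
#' @param qe_spectrum [spectral_curve()] of quantum efficiency.
#' @param read_noise_rms read noise in electrons RMS.
#' @param dark_current dark current in electrons/pixel/s.
#' @param sensor_pixels integer (rows, cols) of the imaging array.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(qe_spectrum = flat_qe(), read_noise_rms = 6,
                         dark_current = 0.05, sensor_pixels = c(1040, 1392)) {
  stopifnot(inherits(qe_spectrum, "spectral_curve"),
            read_noise_rms >= 0, dark_current >= 0)
  structure(list(qe_spectrum = qe_spectrum, read_noise_rms = read_noise_rms,
                 dark_current = dark_current,
                 sensor_pixels = as.integer(sensor_pixels)),
            class = "camera_model")
}

#' Diffraction-limited spot diameter
#'
#' Diameter of the first dark ring of the Airy pattern, `1.22 * lambda / NA`.
#' At the 530-nm emission peak and NA 1.45 this is 445.9 nm, i.e. a spot of
#' about 450 nm — four camera pixels — for a single fluorescent tag.
#'
#' @param wavelength wavelength in nm.
#' @param na numerical aperture.
#' @return first-dark-ring diameter in nm.
#' @examples
#' psf_diameter(530, 1.45)  # ~445.9 nm
#' @export
psf_diameter <- function(wavelength, na) {
  if (any(wavelength <= 0) || any(na <= 0))
    stop("wavelength and na must be positive")
  1.22 * wavelength / na
}

#' Sample-plane pixel size
#'
#' Camera pixel pitch demagnified into the sample plane. With 6.45-um pixels
#' and a 60x objective: 107.5 nm, i.e. 110 nm per pixel at 10-nm rounding.
#'
#' @param camera_pixel_pitch camera pixel pitch in um.
#' @param magnification objective magnification.
#' @return pixel size in the sample plane, nm.
#' @examples
#' sample_pixel_size(6.45, 60)  # 107.5 nm
#' @export
sample_pixel_size <- function(camera_pixel_pitch, magnification) {
  if (any(camera_pixel_pitch <= 0) || any(magnification <= 0))
    stop("pitch and magnification must be positive")
  camera_pixel_pitch * 1000 / magnification
}

#' Collection solid angle of the objective
#'
#' `Omega = 2*pi*(1 - sqrt(1 - NA^2/n^2))` steradians: the cone of light the
#' objective collects from an emitter in a medium of index `n_medium`.
#' Strictly increasing in NA; equals `2*pi` (a full hemisphere) when NA = n.
#'
#' @param na numerical aperture (0 < na <= n_medium).
#' @param n_medium refractive index of the medium.
#' @return solid angle in sr.
#' @examples
#' objective_solid_angle(1.45, 1.56)  # ~3.97 sr
#' @export
objective_solid_angle <- function(na, n_medium) {
  if (any(na < 0) || any(n_medium <= 0)) stop("invalid na or n_medium")
  if (any(na > n_medium)) stop("na must not exceed n_medium")
  2 * pi * (1 - sqrt(1 - (na / n_medium)^2))
}

#' Photon spectral irradiance at the sample
#'
#' The source radiance spectrum is filtered by the excitation filter and the
#' dichroic reflection, converted to a photon rate with the photon energy
#' `h*c/lambda`, and concentrated through the solid angle of the objective:
#' per wavelength, `radiance * T_ex * R_dichroic * Omega * lambda / (h*c)`,
#' in photons s-1 m-2 nm-1.
#'
#' @param source_spectrum radiance [spectral_curve()] (W m-2 sr-1 nm-1).
#' @param excitation_transmission transmission [spectral_curve()].
#' @param dichroic_reflection reflection [spectral_curve()].
#' @param solid_angle collection solid angle in sr.
#' @return a [spectral_curve()] of photon spectral irradiance.
#' @export
photon_spectral_irradiance <- function(source_spectrum,
                                       excitation_transmission,
                                       dichroic_reflection, solid_angle) {
  stopifnot(solid_angle >= 0)
  prod <- sc_product(source_spectrum, excitation_transmission,
                     dichroic_reflection)
  # lambda in nm -> m for the photon energy; result stays per-nm
  lam_m <- prod$wavelength * 1e-9
  spectral_curve(prod$wavelength,
                 prod$value * solid_angle * lam_m / (PLANCK_H * LIGHT_C),
                 unit = "photons s-1 m-2 nm-1")
}

#' Photon absorption rate of one fluorophore
#'
#' `gamma = absorption_cross_section * integral(irradiance d lambda)`.
#'
#' @param irradiance photon spectral irradiance [spectral_curve()].
#' @param absorption_cross_section m2.
#' @return absorbed photons per second.
#' @export
absorbed_photon_rate <- function(irradiance, absorption_cross_section) {
  stopifnot(absorption_cross_section > 0)
  if (any(irradiance$value < 0)) stop("irradiance must be non-negative")
  absorption_cross_section * sc_integral(irradiance)
}

#' Collected photon emission rate of one fluorophore
#'
#' Saturation-corrected emission rate collected into the objective's solid
#' angle: `PER = (Omega / 4 pi) * phi * (1/gamma + t_fl)^-1`.  In the
#' unsaturated limit `gamma * t_fl << 1` this reduces to
#' `(Omega/4 pi) * phi * gamma`; as `gamma -> Inf` it plateaus at the
#' lifetime-limited rate `(Omega/4 pi) * phi / t_fl`.
#'
#' @param phi quantum yield in (0, 1].
#' @param gamma photon absorption rate, photons/s.
#' @param lifetime fluorescence lifetime, s.
#' @param solid_angle collection solid angle, sr.
#' @param saturation_form `"plus"` (default) uses `(1/gamma + t)^-1`;
#'   `"minus"` uses the alternative `(1/gamma - t)^-1` reading.
#' @return collected photons per second.
#' @export
photon_emission_rate <- function(phi, gamma, lifetime, solid_angle,
                                 saturation_form = c("plus", "minus")) {
  saturation_form <- match.arg(saturation_form)
  stopifnot(phi > 0, phi <= 1, gamma >= 0, lifetime > 0, solid_angle >= 0)
  if (gamma == 0) return(0)
  denom <- if (saturation_form == "plus") 1 / gamma + lifetime
           else 1 / gamma - lifetime
  if (denom <= 0) stop("invalid saturation denominator (gamma too large for 'minus' form)")
  (solid_angle / (4 * pi)) * phi / denom
}

#' Signal electrons detected from one fluorophore
#'
#' The collected emission, spectrally distributed over the fluorophore's
#' unit-area emission spectrum, is filtered by the emission filter and the
#' dichroic transmission, converted by the camera QE, and integrated over
#' wavelength and exposure time:
#' `Ne = exposure * integral(PER * S_em(lambda) * T_em * T_dichroic * QE d lambda)`.
#'
#' @param per_spectrum [spectral_curve()] of the emission-rate spectral
#'   density (photons s-1 nm-1), i.e. PER times the unit-area emission
#'   spectrum; see [per_spectrum()].
#' @param emission_transmission transmission [spectral_curve()].
#' @param dichroic_transmission transmission [spectral_curve()].
#' @param qe quantum-efficiency [spectral_curve()].
#' @param exposure exposure time in s.
#' @return detected signal electrons (per fluorophore, per exposure).
#' @export
signal_electrons <- function(per_spectrum, emission_transmission,
                             dichroic_transmission, qe, exposure) {
  stopifnot(exposure > 0)
  exposure * sc_integral(sc_product(per_spectrum, emission_transmission,
                                    dichroic_transmission, qe))
}

#' Emission-rate spectral density
#'
#' Distributes a scalar collected emission rate over a unit-area emission
#' spectrum.
#'
#' @param per collected photon emission rate, photons/s.
#' @param emission_spectrum unit-area [spectral_curve()] (nm-1).
#' @return a [spectral_curve()] in photons s-1 nm-1.
#' @export
per_spectrum <- function(per, emission_spectrum) {
  sc_scale(emission_spectrum, per, unit = "photons s-1 nm-1")
}

#' Mean background electrons per pixel
#'
#' Three contributions: (i) excitation light elastically scattered by the
#' dye (cross-section ~1.1e-13 m2) that leaks through the emission path at
#' the *source* wavelength, where the emission filter transmits only its
#' out-of-band floor; (ii) dark current integrated over the exposure;
#' (iii) a configurable extra background standing in for out-of-focus
#' fluorophores and autofluorescence.  The mean background is subtracted
#' before classification, but its Poisson noise remains in the image.
#'
#' @param irradiance photon spectral irradiance [spectral_curve()] at the
#'   sample (excitation band).
#' @param scattering_cross_section m2.
#' @param emission_transmission_at_source_band transmission of the emission
#'   path at excitation wavelengths (scalar, typically the out-of-band floor
#'   squared for filter + dichroic, or a [spectral_curve()]).
#' @param qe quantum-efficiency [spectral_curve()].
#' @param exposure exposure time in s.
#' @param extra_background electrons/pixel added for out-of-focus and
#'   autofluorescence light (default 0).
#' @param dark_current electrons/pixel/s (default 0).
#' @param solid_angle collection solid angle, sr (collected fraction
#'   `Omega / 4 pi` applied to the scattered light).
#' @return list with `scatter_leakage`, `dark`, `extra` and `total`
#'   mean electrons per pixel.
#' @export
background_electrons <- function(irradiance, scattering_cross_section,
                                 emission_transmission_at_source_band,
                                 qe, exposure, extra_background = 0,
                                 dark_current = 0, solid_angle = 4 * pi) {
  stopifnot(scattering_cross_section >= 0, exposure > 0,
            extra_background >= 0, dark_current >= 0)
  scatter_rate <- scattering_cross_section * sc_integral(irradiance)
  # mean QE over the excitation support of the irradiance
  grid <- irradiance$wavelength
  w <- irradiance$value
  qe_src <- if (sum(w) > 0) sum(sc_value(qe, grid) * w) / sum(w) else 0
  t_em <- if (inherits(emission_transmission_at_source_band, "spectral_curve")) {
    if (sum(w) > 0)
      sum(sc_value(emission_transmission_at_source_band, grid) * w) / sum(w)
    else 0
  } else emission_transmission_at_source_band
  scatter <- scatter_rate * (solid_angle / (4 * pi)) * t_em * qe_src * exposure
  dark <- dark_current * exposure
  list(scatter_leakage = scatter, dark = dark, extra = extra_background,
       total = scatter + dark + extra_background)
}

#' Full photon-budget chain for a configuration
#'
#' Runs the complete radiometric chain — source radiance, excitation filter
#' and dichroic reflection, photon irradiance, absorption, saturation-corrected
#' emission into the collection cone, emission filter, dichroic transmission,
#' camera QE — and returns every intermediate quantity.
#'
#' @param setup an [optical_setup()].
#' @param fluorophore a [fluorophore_model()].
#' @param camera a [camera_model()].
#' @param source radiance [spectral_curve()] (default [led_spectrum()]).
#' @param extra_background electrons/pixel (default 100: out-of-focus +
#'   autofluorescence level typical of these preparations).
#' @param saturation_form passed to [photon_emission_rate()].
#' @return a list of class `photon_budget` with elements `solid_angle`,
#'   `irradiance`, `absorbed_photon_rate`, `emission_rate`,
#'   `signal_electrons`, `background` (list, see [background_electrons()])
#'   and `background_electrons_per_pixel`.
#' @examples
#' b <- photon_budget(optical_setup(), fluorophore_model(), camera_model())
#' b$signal_electrons
#' @export
photon_budget <- function(setup = optical_setup(),
                          fluorophore = fluorophore_model(),
                          camera = camera_model(),
                          source = led_spectrum(),
                          extra_background = 100,
                          saturation_form = "plus") {
  stopifnot(inherits(setup, "optical_setup"),
            inherits(fluorophore, "fluorophore_model"),
            inherits(camera, "camera_model"))
  oob <- setup$out_of_band_transmission
  ex_filter <- tophat_filter(setup$excitation_band, out_of_band = oob)
  em_filter <- tophat_filter(setup$emission_band, out_of_band = oob)
  # dichroic: reflects the excitation band onto the sample, transmits the
  # emission band to the camera
  dichroic_refl <- tophat_filter(setup$excitation_band, out_of_band = oob)
  dichroic_trans <- tophat_filter(setup$emission_band, out_of_band = oob)

  omega <- objective_solid_angle(setup$na, setup$n_medium)
  irr <- photon_spectral_irradiance(source, ex_filter, dichroic_refl, omega)
  gamma <- absorbed_photon_rate(irr, fluorophore$absorption_cross_section)
  per <- photon_emission_rate(fluorophore$quantum_yield, gamma,
                              fluorophore$lifetime, omega,
                              saturation_form = saturation_form)
  ne <- signal_electrons(per_spectrum(per, fluorophore$emission_spectrum),
                         em_filter, dichroic_trans, camera$qe_spectrum,
                         setup$exposure)
  bg <- background_electrons(irr, fluorophore$scattering_cross_section,
                             emission_transmission_at_source_band = oob^2,
                             qe = camera$qe_spectrum,
                             exposure = setup$exposure,
                             extra_background = extra_background,
                             dark_current = camera$dark_current,
                             solid_angle = omega)
  structure(list(solid_angle = omega, irradiance = irr,
                 absorbed_photon_rate = gamma, emission_rate = per,
                 signal_electrons = ne, background = bg,
                 background_electrons_per_pixel = bg$total),
            class = "photon_budget")
}

#' @export
print.photon_budget <- function(x, ...) {
  cat("Photon budget\n")
  cat(sprintf("  solid angle           %.4f sr\n", x$solid_angle))
  cat(sprintf("  absorbed photon rate  %.4g photons/s\n", x$absorbed_photon_rate))
  cat(sprintf("  collected emission    %.4g photons/s\n", x$emission_rate))
  cat(sprintf("  signal electrons      %.4g e-/fluorophore\n", x$signal_electrons))
  cat(sprintf("  background/pixel      %.4g e- (scatter %.3g, dark %.3g, extra %.3g)\n",
              x$background$total, x$background$scatter_leakage,
              x$background$dark, x$background$extra))
  invisible(x)
}
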