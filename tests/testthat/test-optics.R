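test_that("diffraction-limited spot size matches the closed form", {
  expect_equal(psf_diameter(530, 1.45), 445.93, tolerance = 1e-4)
  # "about 450 nm" at nearest-10 rounding
  expect_equal(round(psf_diameter(530, 1.45) / 10) * 10, 450)
  expect_equal(psf_diameter(530, 2.90), psf_diameter(530, 1.45) / 2)
  expect_equal(psf_diameter(1060, 1.45), 2 * psf_diameter(530, 1.45))
  expect_error(psf_diameter(-1, 1.45), "positive")
  expect_error(psf_diameter(530, 0), "positive")
})

test_that("sample-plane pixel size is the demagnified pitch", {
  expect_equal(sample_pixel_size(6.45, 60), 107.5)
  expect_equal(round(sample_pixel_size(6.45, 60) / 10) * 10, 110)
  expect_equal(sample_pixel_size(6.45, 1), 6450)
  expect_equal(sample_pixel_size(13.0, 100), 130)
  expect_error(sample_pixel_size(0, 60), "positive")
})

test_that("objective solid angle follows 2*pi*(1 - sqrt(1 - NA^2/n^2))", {
  expect_equal(objective_solid_angle(1.45, 1.56),
               2 * pi * (1 - sqrt(1 - (1.45 / 1.56)^2)))
  expect_equal(objective_solid_angle(1.45, 1.56), 3.966, tolerance = 1e-3)
  expect_equal(objective_solid_angle(0, 1.56), 0)
  expect_equal(objective_solid_angle(1.56, 1.56), 2 * pi)
  expect_error(objective_solid_angle(1.6, 1.56), "exceed")
  # strictly increasing in NA on (0, n]
  na <- seq(0.1, 1.56, length.out = 50)
  expect_true(all(diff(objective_solid_angle(na, 1.56)) > 0))
})

test_that("photon spectral irradiance converts radiance to photon units", {
  zero <- spectral_curve(c(400, 700), c(0, 0))
  ones <- spectral_curve(c(400, 700), c(1, 1))
  out <- photon_spectral_irradiance(zero, ones, ones, 4)
  expect_true(all(out$value == 0))
  # flat unit radiance, unit transmissions: value = Omega * lambda / (h c)
  h <- 6.62607015e-34; cc <- 2.99792458e8
  out2 <- photon_spectral_irradiance(ones, ones, ones, 2.5)
  expect_equal(sc_value(out2, 530), 2.5 * 530e-9 / (h * cc), tolerance = 1e-12)
})

test_that("absorption and emission rates behave per the saturation model", {
  irr <- spectral_curve(c(460, 500), c(1e20, 1e20))
  g1 <- absorbed_photon_rate(irr, 1.212e-20)
  expect_equal(absorbed_photon_rate(irr, 2 * 1.212e-20), 2 * g1)
  expect_equal(absorbed_photon_rate(spectral_curve(c(460, 500), c(0, 0)),
                                    1e-20), 0)
  expect_equal(photon_emission_rate(0.9, 0, 4e-9, pi), 0)
  # unsaturated limit: phi = 1, Omega = 4*pi -> PER ~ gamma
  expect_equal(photon_emission_rate(1, 100, 1e-9, 4 * pi), 100,
               tolerance = 1e-6)
  # saturation plateau: gamma -> Inf -> (Omega/4pi) * phi / t
  expect_equal(photon_emission_rate(0.9, 1e30, 4e-9, 2 * pi),
               0.5 * 0.9 / 4e-9, tolerance = 1e-6)
  # the alternative "minus" typography reading is exposed as a switch
  expect_gt(photon_emission_rate(0.9, 1e6, 4e-9, pi, "minus"),
            photon_emission_rate(0.9, 1e6, 4e-9, pi, "plus"))
})

test_that("signal electrons: lossless limit and linearity in exposure", {
  em <- af488_emission()
  ones <- spectral_curve(c(350, 750), c(1, 1))
  per <- 500
  ne1 <- signal_electrons(per_spectrum(per, em), ones, ones, ones, 1)
  # all-unity filters and QE: Ne = exposure * PER (unit-area emission)
  expect_equal(ne1, per, tolerance = 1e-9)
  expect_equal(signal_electrons(per_spectrum(per, em), ones, ones, ones, 5),
               5 * ne1, tolerance = 1e-12)
})

test_that("background electrons: dark-current floor and linear scaling", {
  irr <- spectral_curve(c(460, 500), rep(1e22, 2))
  qe <- flat_qe(range = c(400, 700))
  b0 <- background_electrons(irr, 1e-30, 0, qe, exposure = 5,
                             dark_current = 0.05)
  expect_equal(b0$total, 0.25, tolerance = 1e-6)
  b1 <- background_electrons(irr, 1.1e-13, 1e-20, qe, exposure = 5,
                             dark_current = 0.05, solid_angle = 4)
  b2 <- background_electrons(irr, 1.1e-13, 1e-20, qe, exposure = 10,
                             dark_current = 0.05, solid_angle = 4)
  expect_equal(b2$scatter_leakage + b2$dark,
               2 * (b1$scatter_leakage + b1$dark), tolerance = 1e-9)
})

test_that("the default photon chain matches a brute-force trapezoid oracle", {
  h <- 6.62607015e-34; cc <- 2.99792458e8
  grid <- 400:700
  sigma <- 25 / (2 * sqrt(2 * log(2)))
  led <- 1000 * exp(-((grid - 470)^2) / (2 * sigma^2))
  ex <- ifelse(grid >= 465 & grid <= 495, 1, 1e-10)
  omega <- 2 * pi * (1 - sqrt(1 - (1.45 / 1.56)^2))
  irr <- led * ex * ex * omega * (grid * 1e-9) / (h * cc)
  gamma <- 1.212e-20 * pracma::trapz(grid, irr)
  per <- omega / (4 * pi) * 0.92 / (1 / gamma + 4.1e-9)
  eg <- 470:700
  s <- ifelse(eg < 520, 16, 32)
  em_raw <- exp(-((eg - 520)^2) / (2 * s^2))
  em_pdf <- em_raw / pracma::trapz(eg, em_raw)
  emf <- ifelse(eg >= 515 & eg <= 555, 1, 1e-10)
  qe <- ifelse(eg >= 450 & eg <= 650, 0.6, 0)
  ig <- eg[eg <= 650]   # intersection with the QE support
  keep <- eg <= 650
  ne <- 5 * pracma::trapz(ig, (per * em_pdf * emf * emf * qe)[keep])

  b <- photon_budget()
  expect_equal(b$solid_angle, omega, tolerance = 1e-12)
  expect_equal(b$absorbed_photon_rate, gamma, tolerance = 1e-6)
  expect_equal(b$emission_rate, per, tolerance = 1e-6)
  expect_equal(b$signal_electrons, ne, tolerance = 1e-6)
  # frozen regression value of the default chain
  expect_equal(b$signal_electrons, 1062.9704, tolerance = 1e-6)
  # scatter leakage through the doubly blocked emission path is negligible
  # relative to the dark-current term, and tiny against the total background
  expect_lt(b$background$scatter_leakage, b$background$dark)
  expect_lt(b$background$scatter_leakage / b$background$total, 1e-6)
  expect_equal(b$background$total,
               b$background$scatter_leakage + 0.05 * 5 + 100)
})
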