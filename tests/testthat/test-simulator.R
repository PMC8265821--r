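test_that("PSF kernels are unit-sum, odd and symmetric", {
  for (shape in c("airy", "gaussian")) {
    k <- psf_kernel(445.93, 10.75, shape = shape)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_true(nrow(k) %% 2 == 1)
    expect_equal(k, t(k))
    expect_equal(k, k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k)))])
  }
  # first dark ring of the Airy pattern sits at psf_diameter / 2
  k <- psf_kernel(445.93, 10.75)
  ctr <- (nrow(k) + 1) / 2
  r0_px <- 445.93 / 2 / 10.75
  expect_lt(k[ctr, ctr + round(r0_px)] / k[ctr, ctr], 1e-3)
})

test_that("sample_monomer respects the separation and orientation laws", {
  cfg <- sim_config()
  withr::with_seed(42, {
    specs <- replicate(10000, sample_monomer(cfg, n_tags = 2L),
                       simplify = FALSE)
  })
  sep <- vapply(specs, function(s) s$separation, 0)
  expect_true(all(sep >= 150 & sep <= 300))
  se <- sqrt((300 - 150)^2 / 12 / length(sep))
  expect_lt(abs(mean(sep) - 225), 3 * se)
  th <- vapply(specs, function(s) s$orientation, 0)
  expect_true(all(th %in% (-90 + 15 * (0:11))))  # discrete 15-degree grid
  # continuous mode covers the axial range
  cfgc <- sim_config(orientation_mode = "continuous")
  withr::with_seed(43, thc <- replicate(500, sample_monomer(cfgc, 2L)$orientation))
  expect_true(all(thc >= -90 & thc < 90))
  expect_false(all(thc %in% (-90 + 15 * (0:11))))
  # determinism
  s1 <- withr::with_seed(7, sample_monomer(cfg))
  s2 <- withr::with_seed(7, sample_monomer(cfg))
  expect_identical(s1, s2)
})

test_that("render_expected conserves electrons and geometry", {
  cfg <- sim_config()
  flat <- render_expected(list(), cfg)
  expect_equal(flat, matrix(100, 25, 25))

  one <- monomer_spec(c(125, 125), 1L)
  img1 <- render_expected(one, cfg)
  expect_equal(sum(img1) - 625 * 100, 2000, tolerance = 0.01)  # < 1% loss
  # brightest pixel at the tag position; radially symmetric up to binning
  pk <- which(img1 == max(img1), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(13, 13))
  expect_equal(img1, t(img1), tolerance = 1e-9)

  two <- monomer_spec(c(125, 125), 2L, orientation = 0, separation = 300)
  img2 <- render_expected(two, cfg)
  expect_equal(sum(img2) - 625 * 100, 4000, tolerance = 0.01)
  # principal second-moment axis of the noiseless image recovers 0 deg
  expect_lt(abs(second_moment_angle(img2 - 100)), 1)
  # and the oracle recovers orientation within 2 deg for sep >= 200 nm
  for (th in c(-60, -15, 30, 75)) {
    img <- noiseless_fixture(th, sep = 220, config = cfg)
    expect_lt(axial_diff(second_moment_angle(img), th), 2)
  }
})

test_that("shot noise follows the Poisson law and is reproducible", {
  zero <- matrix(0, 5, 5)
  expect_equal(apply_shot_noise(zero), matrix(0L, 5, 5))
  expect_error(apply_shot_noise(matrix(-1, 2, 2)), "non-negative")

  const <- matrix(100, 10, 10)
  withr::with_seed(11, {
    draws <- replicate(10000, apply_shot_noise(const)[1:4])
  })
  se <- sqrt(100 / ncol(draws))
  expect_true(all(abs(rowMeans(draws) - 100) < 3 * se))
  expect_equal(mean(apply(draws, 1, var)), 100, tolerance = 0.1)

  n1 <- withr::with_seed(5, apply_shot_noise(const, read_noise_rms = 6))
  n2 <- withr::with_seed(5, apply_shot_noise(const, read_noise_rms = 6))
  expect_identical(n1, n2)
})

test_that("Monte-Carlo mean of shot-noised frames converges to the render", {
  cfg <- sim_config()
  expected <- render_expected(monomer_spec(c(125, 125), 2L, 30, 250), cfg)
  nrep <- 1000
  acc <- matrix(0, 25, 25)
  withr::with_seed(99, {
    for (r in seq_len(nrep)) acc <- acc + apply_shot_noise(expected)
  })
  z <- (acc / nrep - expected) / sqrt(expected / nrep)
  expect_lt(max(abs(z)), 5)       # per-pixel z-scores bounded
  expect_lt(mean(abs(z) > 2), 0.1)
})

test_that("dataset generation is balanced, consistent and seed-pure", {
  cfg <- sim_config()
  ds <- generate_dataset(26, cfg, seed = 3)
  expect_equal(as.integer(table(ds$labels)), rep(2L, 13))
  # stored label always matches the label recomputed from the truth
  recomputed <- orientation_to_class(ds$truth$orientation_deg, ds$truth$n_tags)
  expect_equal(ds$labels, recomputed)
  expect_true(all(ds$counts >= 0))
  expect_true(all(ds$raw >= ds$counts))
  ds2 <- generate_dataset(26, cfg, seed = 3)
  expect_identical(ds, ds2)
  ds3 <- generate_dataset(26, cfg, seed = 4)
  expect_false(identical(ds$counts, ds3$counts))
  # class histogram uniform within rounding for n not divisible by 13
  ds4 <- generate_dataset(30, cfg, seed = 5)
  expect_true(max(table(ds4$labels)) - min(table(ds4$labels)) <= 1)
  expect_error(generate_dataset(5, cfg), ">= 13")
})

test_that("orientation labels identify -90 with +90 and bin at 15 degrees", {
  expect_equal(orientation_to_class(c(-90, -75, 0, 75), 2L), c(0L, 1L, 6L, 11L))
  expect_equal(orientation_to_class(90, 2L), 0L)        # axial wrap
  expect_equal(orientation_to_class(89, 2L), 0L)
  expect_equal(orientation_to_class(-83, 2L), 0L)
  expect_equal(orientation_to_class(-82, 2L), 1L)
  expect_equal(orientation_to_class(NA, 1L), 12L)
  expect_equal(class_to_orientation(0:2), c(-90, -75, -60))
  expect_true(is.na(class_to_orientation(12L)))
})

test_that("the field must be large enough for the PSF support", {
  expect_error(sim_config(field_size = c(7, 7)), "too small")
})
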