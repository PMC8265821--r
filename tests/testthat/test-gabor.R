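test_that("denoising preserves flat regions and the spot axis", {
  const <- matrix(50, 25, 25)
  out <- denoise_image(const)
  expect_equal(out, const, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(attr(out, "denoise_backend"), "gaussian")

  withr::with_seed(13, noisy <- apply_shot_noise(matrix(200, 25, 25)))
  expect_lt(var(as.numeric(denoise_image(noisy))), var(as.numeric(noisy)))

  # second-moment axis moves < 2 degrees under denoising (45-degree fixture)
  img <- noiseless_fixture(45, sep = 300)
  withr::with_seed(14, noisy45 <- apply_shot_noise(img + 100) - 100)
  before <- second_moment_angle(noisy45)
  after <- second_moment_angle(denoise_image(pmax(noisy45, 0)))
  expect_lt(axial_diff(before, after), 2)
  expect_error(denoise_image(matrix(-1, 3, 3)), "non-negative")
})

test_that("the area gate separates none / single / double at the 7-px rule", {
  expect_equal(gate_single_vs_double(matrix(0, 25, 25))$outcome, "none")
  # exactly 6 pixels above threshold -> single; 7 -> double
  img6 <- matrix(0, 25, 25); img6[10, 1:6] <- 300
  img7 <- matrix(0, 25, 25); img7[10, 1:7] <- 300
  g6 <- gate_single_vs_double(img6)
  g7 <- gate_single_vs_double(img7)
  expect_equal(g6$outcome, "single")
  expect_equal(g6$area, 6L)
  expect_equal(g7$outcome, "double")
  # boundary of the threshold itself: 175 is NOT above threshold
  imgt <- matrix(0, 25, 25); imgt[5, 5] <- 175
  expect_equal(gate_single_vs_double(imgt)$outcome, "none")
  # centroid sits on the mask
  expect_equal(unname(g6$centroid["y"]), 9)  # 0-based row
  expect_equal(unname(g6$centroid["x"]), mean(0:5))
})

test_that("gabor feature maps: nullity, determinism, translation", {
  bank <- gabor_bank_config()
  expect_equal(bank$wavelength, 5)
  expect_length(bank$orientations, 12)
  zero <- matrix(0, 25, 25)
  maps <- gabor_features(zero, bank)
  expect_true(all(vapply(maps, max, 0) == 0))
  expect_error(gabor_features(matrix(0, 5, 5), bank), "larger")
  expect_error(gabor_bank_config(orientations = c(0, 180)), "distinct")

  img <- noiseless_fixture(0, sep = 300)
  m1 <- gabor_features(img, bank)
  m2 <- gabor_features(img, bank)
  expect_identical(m1, m2)
  # feature-map maximum location shifts with the object
  imgL <- noiseless_fixture(0, sep = 300,
                            anchor = c(95, 125))
  imgR <- noiseless_fixture(0, sep = 300,
                            anchor = c(125, 125))
  posL <- which.max(gabor_features(imgL, bank)[["90"]])
  posR <- which.max(gabor_features(imgR, bank)[["90"]])
  cL <- (posL - 1) %/% 25; cR <- (posR - 1) %/% 25
  expect_equal(cR - cL, 3)   # 30 supersampled px = 3 camera px
})

test_that("classification agrees with the second-moment oracle", {
  # noiseless 0-degree 300-nm fixture -> bin containing 0 degrees
  img <- noiseless_fixture(0, sep = 300)
  res <- classify_gabor(img)
  expect_equal(res$label, orientation_to_class(0, 2L))
  expect_equal(res$orientation_deg, 0)
  expect_equal(res$gate$outcome, "double")
  expect_equal(res$denoise_backend, "gaussian")
  # profile maximum is attained at the reported (perpendicular) orientation
  argmax_ori <- as.numeric(names(which.max(res$profile)))
  expect_equal(((argmax_ori + 90 + 90) %% 180) - 90, res$orientation_deg)

  # single-tag fixture: below the area gate -> class 12, no orientation
  ressing <- classify_gabor(noiseless_single_fixture())
  expect_equal(ressing$label, 12L)
  expect_true(is.na(ressing$orientation_deg))

  # oracle agreement on noiseless fixtures with separation >= 250 nm
  withr::with_seed(21, {
    ths <- runif(40, -90, 90)
    seps <- runif(40, 250, 300)
  })
  agree <- vapply(seq_along(ths), function(i) {
    img <- noiseless_fixture(ths[i], seps[i])
    ob <- orientation_to_class(second_moment_angle(img), 2L)
    classify_gabor(img)$label == ob
  }, TRUE)
  expect_gte(mean(agree), 0.95)
})

test_that("rotating a fixture by one 15-degree step shifts the class one bin", {
  labs <- vapply(-90 + 15 * (0:11), function(th) {
    classify_gabor(noiseless_fixture(th, sep = 300))$label
  }, 0L)
  expect_equal(labs, 0:11)
  expect_equal(diff(labs), rep(1L, 11))
})

test_that("errors concentrate on adjacent bins in the noisy regime", {
  # at reduced signal the orientation stage, not the gate, dominates the
  # error budget; misclassified doubles should land next to the true bin
  cfg <- sim_config(signal_electrons = 700)
  ds <- generate_dataset(260, cfg, seed = 77)
  pred <- classify_dataset_gabor(ds, gate_threshold = 75)
  dd <- ds$labels < 12 & !is.na(pred$label) & pred$label < 12
  err <- dd & pred$label != ds$labels
  if (any(err)) {
    bindist <- pmin((pred$label[err] - ds$labels[err]) %% 12,
                    (ds$labels[err] - pred$label[err]) %% 12)
    expect_gt(mean(bindist == 1), 0.5)
  }
  expect_gt(mean((pred$label == ds$labels)[ds$labels < 12], na.rm = TRUE),
            1 / 13)
})

test_that("batch classification equals the single-image path", {
  ds <- generate_dataset(26, sim_config(), seed = 8)
  batch <- classify_dataset_gabor(ds)
  for (i in c(1, 7, 13, 26)) {
    single <- classify_gabor(get_image(ds, i))
    expect_equal(batch$label[i], single$label)
    if (!is.na(single$orientation_deg))
      expect_equal(batch$orientation_deg[i], single$orientation_deg)
    expect_equal(batch$gate_outcome[i], single$gate$outcome)
  }
})
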