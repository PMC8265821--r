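test_that("confusion matrices conserve counts and handle missed detections", {
  truth <- c(0, 0, 1, 5, 12, 12)
  pred <- c(0, 1, 1, 5, 12, NA)
  cm <- confusion_matrix(truth, pred)
  expect_equal(sum(cm), 6)
  expect_equal(as.integer(rowSums(cm)[c("0", "1", "5", "12")]), c(2, 1, 1, 2))
  expect_equal(cm["12", "none"], 1L)
  expect_equal(dim(cm), c(13L, 14L))
})

test_that("accuracy is the normalized trace with per-class recall", {
  ident <- confusion_matrix(0:12, 0:12)
  a <- cm_accuracy(ident)
  expect_equal(a$accuracy, 1)
  expect_equal(unname(a$per_class_recall), rep(1, 13))
  # uniform random predictions sit at chance level ~ 1/13
  withr::with_seed(31, {
    truth <- sample(0:12, 20000, replace = TRUE)
    pred <- sample(0:12, 20000, replace = TRUE)
  })
  acc <- cm_accuracy(confusion_matrix(truth, pred))$accuracy
  expect_equal(acc, 1 / 13, tolerance = 0.15)
  expect_error(cm_accuracy(confusion_matrix(integer(0), integer(0))), "empty")
  # excluding the single-tag class changes the denominator
  ex <- cm_accuracy(ident, exclude_single = TRUE)
  expect_equal(ex$accuracy, 1)
})

test_that("adjacent-bin error counts axial neighbours only", {
  # all errors exactly one bin off (with wrap: 11 -> 0)
  truth <- 0:11
  pred <- (0:11 + 1) %% 12
  expect_equal(adjacent_bin_error(confusion_matrix(truth, pred)), 1)
  # all errors to the orthogonal bin
  pred_orth <- (0:11 + 6) %% 12
  expect_equal(adjacent_bin_error(confusion_matrix(truth, pred_orth)), 0)
  # no misclassifications -> NA with flag
  none <- adjacent_bin_error(confusion_matrix(truth, truth))
  expect_true(is.na(none))
  expect_true(attr(none, "no_errors"))
  # double mistaken for single counts as a non-adjacent error
  mix <- confusion_matrix(c(0, 0), c(1, 12))
  expect_equal(adjacent_bin_error(mix), 0.5)
})

test_that("orientation dispersion: naive vs axial about the wrap", {
  tr <- sequence_track(1, rep(4L, 8), rep(-30, 8))
  d <- orientation_dispersion(tr)
  expect_equal(d$naive_sd, 0)
  expect_equal(d$axial_sd, 0)
  # {+85, -85}: naive SD is huge, axial SD is 10/sqrt(2) about the wrap
  tr2 <- sequence_track(2, c(4L, 4L), c(85, -85))
  d2 <- orientation_dispersion(tr2)
  expect_equal(d2$naive_sd, sd(c(85, -85)))          # = 85 * sqrt(2)
  expect_equal(d2$naive_sd, 120.2082, tolerance = 1e-6)
  expect_equal(d2$axial_sd, 10 / sqrt(2), tolerance = 1e-9)
  # single-tag frames are excluded; < 2 usable frames flags as undefined
  tr3 <- sequence_track(3, c(12L, 12L, 4L), c(NA, NA, 10))
  d3 <- orientation_dispersion(tr3)
  expect_true(is.na(d3$naive_sd))
  expect_true(attr(d3, "insufficient"))
  expect_equal(d3$n_used, 1)
})

test_that("dispersion under Poisson re-draws of one monomer is bounded", {
  cfg <- sim_config()
  spec <- monomer_spec(c(125, 125), 2L, orientation = 20, separation = 220)
  expected <- render_expected(spec, cfg)
  withr::with_seed(41, {
    oris <- vapply(1:8, function(t) {
      img <- pmax(apply_shot_noise(expected, cfg$read_noise_rms) - 100, 0)
      classify_gabor(img)$orientation_deg
    }, 0)
  })
  tr <- sequence_track(1, orientation_to_class(oris, 2L), oris)
  d <- orientation_dispersion(tr)
  expect_gte(d$axial_sd, 0)
  expect_lt(d$axial_sd, 90 / sqrt(3))   # uniform-angle ceiling
})

test_that("photobleach drift matches closed forms and the Poisson oracle", {
  f <- matrix(100, 10, 10)
  expect_equal(photobleach_drift(list(f, f)),
               list(mean = 0, sd = 0, n_pairs = 1))
  expect_equal(photobleach_drift(list(f, f - 5))$mean, 5)
  expect_equal(photobleach_drift(list(f, f - 5))$sd, 0)
  expect_error(photobleach_drift(list(f, matrix(0, 3, 3))), "shape")
  expect_error(photobleach_drift(list(f)), ">= 2")
  # two independent Poisson draws of one expected image:
  # mean difference ~ 0, SD ~ sqrt(2 * rate)
  rate <- 400
  withr::with_seed(51, {
    a <- apply_shot_noise(matrix(rate, 100, 100))
    b <- apply_shot_noise(matrix(rate, 100, 100))
  })
  pb <- photobleach_drift(list(a, b))
  expect_equal(pb$mean, 0, tolerance = 3 * sqrt(2 * rate / 1e4))
  expect_equal(pb$sd, sqrt(2 * rate), tolerance = 0.05)
})

test_that("tracking links candidates across frames by nearest centroid", {
  cfg <- sim_config(field_size = c(40, 40))
  spec <- monomer_spec(c(200, 200), 2L, orientation = -45, separation = 280)
  expected <- render_expected(spec, cfg)
  withr::with_seed(61, {
    frames <- lapply(1:3, function(t) {
      pmax(apply_shot_noise(expected, cfg$read_noise_rms) - 100, 0)
    })
  })
  tracks <- track_monomers(frames, method = "gabor")
  expect_length(tracks, 1)
  tr <- tracks[[1]]
  expect_s3_class(tr, "sequence_track")
  expect_length(tr$labels, 3)
  expect_equal(tr$timestamps, c(0, 10, 20))
  expect_true(all(!is.na(tr$labels)))
  expect_true(all(axial_diff(tr$orientations_deg, -45) <= 15))
  expect_length(track_monomers(list(matrix(0, 30, 30), matrix(0, 30, 30))), 0)
})

test_that("reports render plots and a summary that round-trips", {
  out <- withr::local_tempdir()
  cm <- confusion_matrix(c(0:12, 0), c(0:12, 1))
  res <- classify_gabor(noiseless_fixture(30, 300))
  tr <- sequence_track(1, c(4L, 4L, 12L), c(25, 28, NA))
  files <- report(list(confusion = list(demo = cm),
                       profiles = list(demo = res),
                       tracks = list(tr),
                       metrics = list(note_value = 1.5)), out)
  expect_true(all(file.exists(files)))
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(summ$accuracy_demo, 13 / 14, tolerance = 1e-9)
  expect_equal(summ$note_value, 1.5)
  expect_warning(report(list(), withr::local_tempdir()), "empty")
})
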