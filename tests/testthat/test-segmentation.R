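test_that("feature bank configuration validates its scales", {
  expect_error(feature_bank_config(intensity_sigmas_px = c(2, 1)), "sorted")
  expect_error(feature_bank_config(edge_texture_sigmas_px = c(-1, 2)),
               "positive")
  expect_error(feature_bank_config(kinds = character(0)), "feature kind")
  cfg <- feature_bank_config()
  expect_equal(cfg$intensity_sigmas_px, c(1.6, 2.3, 3.5, 5.0))
  expect_equal(cfg$edge_texture_sigmas_px, c(0.07, 0.7, 1.6, 3.5, 5.0))
})

test_that("feature planes obey calculus identities on simple images", {
  const <- matrix(42, 40, 40)
  b <- compute_feature_bank(const)
  nm <- dimnames(b)[[3]]
  for (k in which(grepl("^gaussian", nm))) {
    expect_equal(max(abs(b[, , k] - 42)), 0, tolerance = 1e-10)
  }
  for (k in which(grepl("^(gradmag|log)", nm))) {
    expect_equal(max(abs(b[, , k])), 0, tolerance = 1e-8)
  }

  # single bright pixel: smoothing conserves total mass (reflective boundary)
  spot <- matrix(0, 40, 40); spot[20, 20] <- 1000
  bs <- compute_feature_bank(spot, feature_bank_config(kinds = "gaussian"))
  for (k in seq_len(dim(bs)[3])) {
    expect_lt(abs(sum(bs[, , k]) / 1000 - 1), 0.001)
  }

  # linear ramp: gradient magnitude constant in the interior (margin wider
  # than the kernel support)
  ramp <- matrix(rep(seq_len(40), each = 40), 40, 40, byrow = TRUE)
  br <- compute_feature_bank(
    ramp, feature_bank_config(edge_texture_sigmas_px = c(0.7, 1.6),
                              kinds = "gradient"))
  for (k in 1:2) {
    interior <- br[10:30, 10:30, k]
    expect_lt(diff(range(interior)), 1e-8)
  }

  expect_error(compute_feature_bank(const,
    feature_bank_config(intensity_sigmas_px = c(1.6, 30))), "sigma")
})

test_that("classifier separates a two-intensity scene and is deterministic", {
  sc <- fixture_scene(seed = 55, time_hr = 4)
  bank <- compute_feature_bank(sc$dye)
  lab <- truth_labels(sc, n_per_class = 500, seed = 2)
  m1 <- train_pixel_classifier(bank, lab, seed = 11)
  expect_gte(m1$holdout_accuracy, 0.99)

  m2 <- train_pixel_classifier(bank, lab, seed = 11)
  probe <- fixture_scene(seed = 56, time_hr = 4)
  expect_identical(predict_probability(m1, probe$dye),
                   predict_probability(m2, probe$dye))

  lab_one <- lab; lab_one[lab_one == "droplet"] <- NA
  expect_error(train_pixel_classifier(bank, lab_one, seed = 1), ">= 50")
  lab_few <- matrix(NA_character_, 128, 128)
  lab_few[1:20] <- "droplet"; lab_few[30:49] <- "background"
  expect_error(train_pixel_classifier(bank, lab_few, seed = 1), ">= 50")
})

test_that("probability maps are calibrated on separable regions", {
  model <- fixture_classifier()
  sc <- fixture_scene(seed = 77, time_hr = 5)
  pm <- predict_probability(model, sc$dye)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_equal(dim(pm), dim(sc$dye$pixels))
  core <- sc$truth$droplet_mask & !sc$truth$rim_mask
  bg <- !dilate_mask(sc$truth$droplet_mask, 2) & sc$truth$roi$mask &
    !sc$truth$lumen_mask
  expect_gte(mean(pm[core]), 0.9)
  expect_lte(mean(pm[bg]), 0.1)
  expect_error(predict_probability(list(), sc$dye), "pixel_classifier")
})

test_that("binarize thresholds, filters small objects, and is monotone", {
  expect_equal(sum(binarize(matrix(0.4, 8, 8), 0.5)), 0)
  pm <- matrix(0, 16, 16); pm[5, 5:7] <- 0.9       # 3-px blob
  expect_equal(sum(binarize(pm, 0.5, min_object_px = 5)), 0)
  expect_equal(sum(binarize(pm, 0.5, min_object_px = 3)), 3)
  expect_error(binarize(pm, 1.2), "threshold")

  # diagonal chains are one 8-connected object
  diag_pm <- matrix(0, 10, 10)
  diag_pm[cbind(1:5, 1:5)] <- 0.9
  expect_equal(sum(binarize(diag_pm, 0.5, min_object_px = 5)), 5)

  set.seed(8)
  rnd <- matrix(runif(64 * 64), 64, 64)
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    lo <- binarize(rnd, th, min_object_px = 1)
    hi <- binarize(rnd, min(th + 0.2, 0.99), min_object_px = 1)
    expect_true(all(lo | !hi))  # raising the threshold never adds pixels
  }
})

test_that("segmentation recovers truth masks on synthetic scenes", {
  model <- fixture_classifier()
  sc <- fixture_scene(seed = 91, time_hr = 6)
  seg <- segment_image(model, sc$dye)
  expect_identical(seg$droplet_mask,
                   binarize(seg$probability_map, seg$threshold))
  expect_gte(mask_iou(seg$droplet_mask, sc$truth$droplet_mask), 0.7)

  # noiseless, high-contrast scene: near-perfect recovery
  sc0 <- fixture_scene(seed = 92, time_hr = 6, read_noise_sd = 0,
                       poisson_noise = FALSE)
  expect_gte(mask_iou(segment_image(model, sc0$dye)$droplet_mask,
                      sc0$truth$droplet_mask), 0.9)
})

test_that("classifier serialization round-trips bit-identically", {
  model <- fixture_classifier()
  p <- withr::local_tempfile(fileext = ".rds")
  save_classifier(model, p)
  back <- load_classifier(p)
  sc <- fixture_scene(seed = 93, time_hr = 3)
  expect_identical(predict_probability(model, sc$dye),
                   predict_probability(back, sc$dye))
})
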