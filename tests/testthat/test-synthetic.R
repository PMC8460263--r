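test_that("scene generation is deterministic given params and seed", {
  s1 <- fixture_scene(seed = 3, time_hr = 5)
  s2 <- fixture_scene(seed = 3, time_hr = 5)
  expect_identical(s1$dye$pixels, s2$dye$pixels)
  expect_identical(s1$protein$pixels, s2$protein$pixels)
  expect_identical(s1$truth$radii, s2$truth$radii)
  s3 <- fixture_scene(seed = 4, time_hr = 5)
  expect_false(identical(s1$dye$pixels, s3$dye$pixels))
})

test_that("noiseless rendering conserves the configured intensities exactly", {
  sp <- scene_params(read_noise_sd = 0, poisson_noise = FALSE, seed = 2)
  sch <- protein_schedule("plin2_like")
  sc <- make_droplet_scene(sp, sch, 6)
  tr <- sc$truth
  core <- tr$droplet_mask & !tr$rim_mask
  expect_true(all(sc$dye$pixels[tr$droplet_mask] ==
                    sp$droplet_core_dye_intensity))
  cyto_px <- tr$roi$mask & !tr$droplet_mask & !tr$lumen_mask
  expect_true(all(sc$dye$pixels[cyto_px] == sp$cytoplasm_dye_intensity))
  expect_true(all(sc$dye$pixels[tr$lumen_mask] == sp$lumen_dye_intensity))
  # protein channel: cyto everywhere in ROI, plus rim component on the shell
  rim_v <- round(sch$cyto_intensity(6) + sch$rim_intensity(6))
  cyto_v <- round(sch$cyto_intensity(6))
  expect_true(all(sc$protein$pixels[tr$rim_mask] == rim_v))
  expect_true(all(sc$protein$pixels[tr$roi$mask & !tr$rim_mask] == cyto_v))
  expect_equal(tr$true_rim_mean, sch$cyto_intensity(6) + sch$rim_intensity(6))
  expect_equal(tr$true_cyto_mean, sch$cyto_intensity(6))
})

test_that("droplet-free scenes have a uniform protein channel", {
  sp <- scene_params(n_droplets = 0, read_noise_sd = 0, poisson_noise = FALSE,
                     seed = 1)
  sc <- make_droplet_scene(sp, protein_schedule("plin3_like"), 0)
  expect_equal(sum(sc$truth$rim_mask), 0)
  expect_equal(length(unique(sc$protein$pixels[sc$truth$roi$mask])), 1L)
})

test_that("droplet placement respects geometry and density limits", {
  sc <- fixture_scene(seed = 9)
  tr <- sc$truth
  # non-overlap: pairwise center distance exceeds the radius sum
  d <- as.matrix(dist(tr$centers[, c(1, 2)]))
  rsum <- outer(tr$radii, tr$radii, `+`)
  expect_true(all(d[upper.tri(d)] > rsum[upper.tri(rsum)]))
  expect_true(all(tr$radii >= 2))
  expect_false(any(tr$droplet_mask & tr$lumen_mask))
  # infeasible density errors out
  expect_error(
    make_droplet_scene(scene_params(n_droplets = 500, seed = 1),
                       protein_schedule("plin2_like"), 2),
    "infeasible")
})

test_that("noise model obeys its limiting cases and moments", {
  z <- matrix(0, 10, 10)
  expect_true(all(apply_noise(z, read_noise_sd = 0, seed = 1) == 0))
  # clamping: clean means far above the dynamic range saturate
  big <- matrix(2^12 * 2, 5, 5)
  expect_true(all(apply_noise(big, read_noise_sd = 0, bit_depth = 12,
                              seed = 1) == 4095))
  expect_error(apply_noise(z, read_noise_sd = -1), "read_noise_sd")
  expect_error(apply_noise(matrix(-3, 2, 2)), ">= 0")
  # Poisson moment check: mean of 1e4 draws at mean 100 within 3*10/sqrt(1e4)
  m <- apply_noise(matrix(100, 100, 100), read_noise_sd = 0, seed = 4)
  expect_lt(abs(mean(m) - 100), 0.3)
  # determinism
  m2 <- apply_noise(matrix(100, 100, 100), read_noise_sd = 0, seed = 4)
  expect_identical(m, m2)
})

test_that("rendered cytoplasm mean matches the schedule (law of large numbers)", {
  sc <- fixture_scene(seed = 1, time_hr = 6)
  sch <- protein_schedule("plin2_like")
  cyto_px <- sc$truth$roi$mask & !sc$truth$rim_mask
  expect_gte(sum(cyto_px), 1e4)
  expect_lt(abs(mean(sc$protein$pixels[cyto_px]) / sch$cyto_intensity(6) - 1),
            0.02)
})

test_that("protein schedules encode the recruitment order", {
  tg <- seq(0, 30, by = 0.25)

  p3 <- protein_schedule("plin3_like")
  expect_gt(p3$cyto_intensity(0), 0)
  contrast <- p3$rim_intensity(tg) - p3$cyto_intensity(tg)
  pk <- which.max(contrast)
  expect_true(all(diff(contrast[pk:length(tg)]) <= 0))

  p2 <- protein_schedule("plin2_like")
  expect_equal(p2$rim_intensity(0), 0)
  rim2 <- p2$rim_intensity(tg)
  amax <- tg[which.max(rim2)]
  expect_gte(amax, p2$params$onset_hr)
  expect_lte(amax, p2$params$decline_onset_hr)
  expect_gt(max(rim2), p2$rim_intensity(30))  # late decline

  ov <- protein_schedule("overexpressed_like")
  early <- ov$rim_intensity(c(0.25, 0.75, 1.5, 3))
  expect_true(all(diff(early) > 0))           # rising from the first samples
  expect_true(all(is.finite(c(rim2, early, contrast))))
})

test_that("whole-mount series isolates organ signal from autofluorescence", {
  # zero organ signal: reporters and wild types are exchangeable
  s0 <- make_wholemount_series(3, c(0, 2), function(t) 0, autofluor_level = 40,
                               seed = 2, variation_sd = 0, read_noise_sd = 0,
                               poisson = FALSE)
  ints <- vapply(s0$images, function(m) raw_integrated_density(m, s0$roi),
                 numeric(1))
  expect_equal(length(unique(ints)), 1L)

  # zero autofluorescence, noise off: wild-type integrated density is 0
  s1 <- make_wholemount_series(2, 1, function(t) 50, autofluor_level = 0,
                               seed = 3, variation_sd = 0, read_noise_sd = 0,
                               poisson = FALSE)
  wt <- Filter(function(m) m$genotype_label == "wild_type", s1$images)
  expect_true(all(vapply(wt, function(m) raw_integrated_density(m, s1$roi),
                         numeric(1)) == 0))
  expect_error(make_wholemount_series(2, numeric(0), function(t) 0, 1, 1),
               "non-empty")
  expect_error(make_wholemount_series(1, 1, function(t) 0, 1, 1),
               "wild-type")
})

test_that("corrected whole-mount series passes a linear signal through exactly", {
  sig <- function(t) 80 * t
  s <- make_wholemount_series(3, c(0, 2, 4, 6), sig, autofluor_level = 30,
                              seed = 5, variation_sd = 0, read_noise_sd = 0,
                              poisson = FALSE)
  pts <- quantify_wholemount(s$images, s$roi)
  cor_pts <- autofluorescence_correct(pts)
  rep_pts <- cor_pts[cor_pts$genotype_label == "reporter", ]
  organ_px <- sum(s$roi$mask)
  expect_equal(rep_pts$corrected_value, sig(rep_pts$time_hr) * organ_px)
})
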