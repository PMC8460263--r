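test_that("orthogonal regression recovers exact linear relations", {
  set.seed(3)
  px <- matrix(sample(1:200, 100, TRUE), 10, 10)
  roi <- full_roi(c(10, 10))
  res <- costes_threshold(px, 2 * px, roi)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 0)
  expect_equal(res$threshold_ch2, res$slope * res$threshold_ch1 + res$intercept)

  expect_error(costes_threshold(matrix(5, 10, 10), px, roi), "channel 1")
  expect_error(costes_threshold(px, matrix(5, 10, 10), roi), "channel 2")
  expect_error(costes_threshold(px[1:3, 1:3, drop = FALSE],
                                px[1:3, 1:3, drop = FALSE],
                                full_roi(c(3, 3))), "50")
})

test_that("perfect anticorrelation terminates immediately at the maximum", {
  set.seed(5)
  x <- matrix(sample(1:60, 64, TRUE), 8, 8)
  y <- -x + 100
  res <- costes_threshold(x, y, full_roi(c(8, 8)))
  expect_equal(res$slope, -1)
  expect_equal(res$intercept, 100)
  # the linked below-threshold set {x < T1 & y < -T1 + 100} is empty at every
  # T1, so the search ends at the first (maximum) candidate with r undefined
  expect_equal(res$threshold_ch1, max(x))
  expect_false(res$converged)
  expect_true(is.na(res$pearson_below))
})

test_that("manders coefficients match hand-enumerable instances", {
  roi <- full_roi(c(3, 3))
  ch <- matrix(1:9, 3, 3)
  tm <- manders_coefficients(ch, ch, 0, 0, roi)
  expect_equal(tm$tM1, 1)
  expect_equal(tm$tM2, 1)

  a <- matrix(c(5, 0, 5, 0, 5, 0, 5, 0, 5), 3, 3)
  b <- matrix(c(0, 7, 0, 7, 0, 7, 0, 7, 0), 3, 3)
  tm0 <- manders_coefficients(a, b, 0, 0, roi)
  expect_equal(tm0$tM1, 0)
  expect_equal(tm0$tM2, 0)

  # 3x3 worked instance: ch1 = 1..9 row-major, ch2 = 10 on alternating pixels
  ch1 <- matrix(1:9, 3, 3, byrow = TRUE)
  ch2 <- matrix(rep(c(10, 0), length.out = 9), 3, 3, byrow = TRUE)
  tm1 <- manders_coefficients(ch1, ch2, 0, 5, roi)
  bf <- bf_manders(as.vector(ch1), as.vector(ch2), 0, 5, as.vector(roi$mask))
  expect_equal(tm1$tM1, bf$tM1)
  expect_equal(tm1$tM1, sum(ch1[ch2 > 5]) / 45)
  expect_true(is.na(manders_coefficients(matrix(0, 3, 3), ch2, 0, 0,
                                         roi)$tM1))
})

test_that("iterative threshold search matches exhaustive enumeration", {
  set.seed(17)
  for (rep in 1:20) {
    base <- matrix(rpois(64, 40), 8, 8)
    x <- base + matrix(rpois(64, 10), 8, 8)
    y <- round(1.4 * base) + matrix(rpois(64, 10), 8, 8)
    roi <- full_roi(c(8, 8))
    res <- costes_threshold(x, y, roi)
    bf <- bf_costes_threshold(as.vector(x)[roi$mask], as.vector(y)[roi$mask],
                              res$slope, res$intercept)
    expect_identical(res$threshold_ch1, bf$threshold_ch1)
    expect_identical(res$converged, bf$converged)

    tm <- manders_coefficients(x, y, res$threshold_ch1, res$threshold_ch2, roi)
    bfm <- bf_manders(as.vector(x), as.vector(y), res$threshold_ch1,
                      res$threshold_ch2, as.vector(roi$mask))
    expect_identical(tm, bfm)
  }
})

test_that("coefficients are invariant under channel rescaling", {
  set.seed(23)
  base <- matrix(rpois(400, 50), 20, 20)
  x <- base + matrix(rpois(400, 8), 20, 20)
  y <- base + matrix(rpois(400, 8), 20, 20)
  roi <- full_roi(c(20, 20))
  res <- costes_threshold(x, y, roi)
  k <- 3
  res_k <- costes_threshold(k * x, y, roi)
  expect_equal(res_k$slope, res$slope / k)
  expect_equal(res_k$threshold_ch1, k * res$threshold_ch1)
  expect_equal(res_k$threshold_ch2, res$threshold_ch2)
  tm <- manders_coefficients(x, y, res$threshold_ch1, res$threshold_ch2, roi)
  tm_k <- manders_coefficients(k * x, y, res_k$threshold_ch1,
                               res_k$threshold_ch2, roi)
  expect_equal(tm_k$tM1, tm$tM1)
  expect_equal(tm_k$tM2, tm$tM2)
})

test_that("tM1 is non-increasing in the channel-2 threshold", {
  set.seed(29)
  x <- matrix(rpois(256, 30), 16, 16)
  y <- matrix(rpois(256, 30), 16, 16)
  roi <- full_roi(c(16, 16))
  ths <- c(0, 10, 20, 30, 40, 60)
  tms <- vapply(ths, function(t2) {
    manders_coefficients(x, y, 0, t2, roi)$tM1
  }, numeric(1))
  expect_true(all(diff(tms) <= 0))
})

test_that("the automatic threshold separates rim signal from cytoplasm", {
  # on scenes with occupied rims the search converges and places the protein
  # threshold between the diffuse cytoplasmic level and the rim level, so the
  # Manders fraction counts rim-associated dye signal only
  sch <- protein_schedule("plin2_like")
  t <- sch$params$decline_onset_hr
  for (seed in c(301, 302, 303)) {
    sc <- fixture_scene(seed = seed, time_hr = t)
    res <- coloc_analysis(sc$dye, sc$protein, sc$truth$roi)
    expect_true(res$converged)
    expect_gt(res$threshold_ch2, sch$cyto_intensity(t))
    expect_lt(res$threshold_ch2, sch$cyto_intensity(t) + sch$rim_intensity(t))
    expect_gt(res$tM1, 0)
    expect_lte(res$tM1, 1)
    expect_lte(res$pearson_below, 0)
  }
})
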