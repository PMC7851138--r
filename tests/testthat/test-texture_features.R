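test_that("first-order moments are population moments with non-excess kurtosis", {
  # constant input: mean/sd valid, shape statistics undefined
  f <- first_order_features(c(2, 2, 2, 2))
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["sd"]), 0)
  expect_true(is.na(f["kurtosis"]))
  expect_true(is.na(f["skewness"]))

  # population sd (divide by N), symmetric sample has zero skewness
  f <- first_order_features(c(1, 2, 3))
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["sd"]), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(f["skewness"]), 0, tolerance = 1e-12)

  # large normal sample: kurtosis near 3 (not 0), skewness near 0
  set.seed(42)
  x <- rnorm(1e5)
  f <- first_order_features(x)
  expect_lt(abs(f["kurtosis"] - 3), 0.1)
  expect_lt(abs(f["skewness"]), 0.05)

  expect_error(first_order_features(5), "2 voxels")
})

test_that("first-order features are invariant to voxel order", {
  set.seed(7)
  x <- rnorm(200, 50, 4)
  expect_equal(first_order_features(x), first_order_features(sample(x)))
})

test_that("quantization bins [lo, hi] linearly into G levels with clamping", {
  q <- quantize(0:63, 64, "global", c(0, 63))
  expect_identical(q$levels, 0:63)

  # hand binning: bin edge at 15
  q <- quantize(c(0, 10, 20, 30), 2, "global", c(0, 30))
  expect_identical(q$levels, c(0L, 0L, 1L, 1L))

  # out-of-range values clamp to the extreme bins
  q <- quantize(c(-5, 500), 8, "global", c(0, 100))
  expect_identical(q$levels, c(0L, 7L))

  # constant ROI under roi_minmax degenerates to level 0 everywhere
  q <- quantize(rep(3.3, 10), 16, "roi_minmax")
  expect_true(all(q$levels == 0L))

  expect_error(quantize(1:5, 1, "global", c(0, 1)), "G")
  expect_error(quantize(1:5, 4, "global", c(1, 1)), "hi > lo")
})

test_that("GLCM of a constant region is a single diagonal cell", {
  lev <- array(0L, c(3, 3, 1))
  g <- build_glcm(as_quantized(lev, 4), array(TRUE, c(3, 3, 1)))
  expect_equal(g$P[1, 1], 1)
  expect_equal(sum(g$P), 1)
})

test_that("checkerboard GLCM at theta = 0 only matches hand enumeration", {
  lev <- array(c(0L, 1L, 1L, 0L), c(2, 2, 1))
  g <- build_glcm(as_quantized(lev, 2), array(TRUE, c(2, 2, 1)), directions = 0)
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("GLCM matches the brute-force pair enumeration oracle", {
  set.seed(123)
  for (rep in 1:25) {
    roi <- random_roi(c(6, 6, 3), G = 8)
    q <- as_quantized(roi$levels, roi$G)
    g <- build_glcm(q, roi$mask)
    expect_equal(g$P, oracle_glcm(roi$levels, roi$mask, roi$G),
                 tolerance = 1e-12)
    g3 <- build_glcm(q, roi$mask, glcm_3d = TRUE)
    expect_equal(g3$P, oracle_glcm(roi$levels, roi$mask, roi$G, use_3d = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("GLCM is symmetric with unit mass and errors on a pairless mask", {
  set.seed(5)
  roi <- random_roi(c(5, 5, 2), G = 6)
  g <- build_glcm(as_quantized(roi$levels, roi$G), roi$mask)
  expect_equal(g$P, t(g$P), tolerance = 1e-12)
  expect_equal(sum(g$P), 1, tolerance = 1e-12)

  single <- array(FALSE, c(4, 4, 2)); single[2, 2, 1] <- TRUE
  expect_error(build_glcm(as_quantized(array(0L, c(4, 4, 2)), 4), single),
               "degenerate GLCM")
})

test_that("degenerate single-cell GLCM yields closed-form features", {
  P <- matrix(0, 4, 4); P[1, 1] <- 1
  f <- glcm_features(P)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["idm"]), 1)
  expect_equal(unname(f["sumV"]), 0)
  expect_true(is.na(f["correlation"]))  # zero marginal SD
})

test_that("checkerboard GLCM features match hand evaluation of each sum", {
  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f <- glcm_features(P)
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["entropy"]), log(2), tolerance = 1e-12)
  expect_equal(unname(f["homogeneity"]), 0.5)
  expect_equal(unname(f["idm"]), 0.5)
  expect_equal(unname(f["sumA"]), 1)
  expect_equal(unname(f["sumV"]), 0)
  expect_equal(unname(f["correlation"]), -1)
})

test_that("all eight co-occurrence features match the literal-sum oracle", {
  set.seed(99)
  for (rep in 1:30) {
    C <- matrix(rexp(64), 8, 8)
    P <- (C + t(C)) / sum(C + t(C))
    expect_equal(glcm_features(P), oracle_glcm_features(P), tolerance = 1e-10)
  }
})

test_that("feature bounds hold on random GLCMs", {
  set.seed(17)
  for (rep in 1:20) {
    G <- sample(3:12, 1)
    C <- matrix(rexp(G * G), G, G)
    P <- (C + t(C)) / sum(C + t(C))
    f <- glcm_features(P)
    expect_lte(f["entropy"], 2 * log(G))
    expect_gte(f["entropy"], 0)
    expect_gt(f["homogeneity"], 0); expect_lte(f["homogeneity"], 1)
    expect_gt(f["idm"], 0); expect_lte(f["idm"], 1)
    expect_gte(f["contrast"], 0)
    expect_lte(f["contrast"], (G - 1)^2)
    expect_gte(f["sumV"], 0)
    expect_gte(f["sumSQR"], 0)
  }
})

test_that("entropy log base is configurable", {
  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(unname(glcm_features(P, log_base = 2)["entropy"]), 1)
})

test_that("hemisphere averaging follows the element-wise mean contract", {
  set.seed(31)
  img <- array(rnorm(6 * 6 * 4, 100, 5), c(6, 6, 4))
  mask_l <- array(FALSE, dim(img)); mask_l[1:3, 1:4, 1:3] <- TRUE
  mask_r <- array(FALSE, dim(img)); mask_r[4:6, 1:4, 1:3] <- TRUE
  p <- texture_params(G = 8, mode = "roi_minmax")

  # identical masks: average equals either side
  same <- structure_features(img, mask_l, mask_l, p)
  expect_equal(same$features, same$left)

  # general case: average is the element-wise mean of the two sides
  sf <- structure_features(img, mask_l, mask_r, p)
  expect_equal(sf$features, (sf$left + sf$right) / 2)

  # a constant hemisphere contributes entropy 0 and an undefined skewness
  # that propagates through the average
  img2 <- img; img2[mask_l] <- 50
  sf2 <- structure_features(img2, mask_l, mask_r, p)
  expect_equal(unname(sf2$features["entropy"]),
               unname(sf2$right["entropy"]) / 2)
  expect_true(is.na(sf2$features["skewness"]))
  expect_false(is.na(sf2$right["skewness"]))

  expect_error(structure_features(img, NULL, mask_r, p), "missing left")
  single <- structure_features(img, NULL, mask_r, p, allow_single = TRUE)
  expect_equal(single$features, sf$right)
})

test_that("second-order features are affine-invariant under roi_minmax", {
  set.seed(77)
  p <- texture_params(G = 16, mode = "roi_minmax")
  for (rep in 1:10) {
    roi <- random_intensity_roi()
    base <- pdtexture:::roi_features(roi$image, roi$mask, p)
    shifted <- pdtexture:::roi_features(roi$image + 37.5, roi$mask, p)
    scaled <- pdtexture:::roi_features(roi$image * 3.2 - 11, roi$mask, p)
    so <- c("homogeneity", "contrast", "entropy", "correlation", "sumSQR",
            "sumA", "sumV", "idm")
    expect_equal(base[so], shifted[so], tolerance = 1e-12)
    expect_equal(base[so], scaled[so], tolerance = 1e-12)
  }
})
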