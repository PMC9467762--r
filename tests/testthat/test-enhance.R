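test_that("gray-level histogram counts match a brute-force tally", {
  img <- matrix(c(0L, 255L, 0L, 255L), 2, 2)
  h <- gray_histogram(img)
  expect_identical(h$counts[1], 2L)
  expect_identical(h$counts[256], 2L)
  expect_identical(sum(h$counts), 4L)
  const <- matrix(9L, 5, 5)
  expect_identical(gray_histogram(const)$counts[10], 25L)
  set.seed(21)
  rnd <- matrix(sample.int(256, 256, replace = TRUE) - 1L, 16, 16)
  tally <- integer(256)
  for (v in as.vector(rnd)) tally[v + 1] <- tally[v + 1] + 1L
  expect_identical(gray_histogram(rnd)$counts, tally)
})

test_that("histogram equalization follows the CDF mapping and handles degenerate input", {
  expect_identical(equalize_histogram(matrix(37L, 8, 8)), matrix(37L, 8, 8))
  # two occupied levels in equal proportion: lowest occupied level carries
  # cdf_min, so it maps to 0 and the upper level to L - 1
  img <- matrix(c(rep(10L, 32), rep(20L, 32)), 8, 8)
  eq <- equalize_histogram(img)
  expect_identical(sort(unique(as.vector(eq))), c(0L, 255L))
  expect_true(all(eq[img == 10L] == 0L))
  # monotone: sorted distinct input levels stay sorted in the output
  set.seed(8)
  rnd <- matrix(sample.int(200, 400, replace = TRUE) + 20L, 20, 20)
  eq2 <- equalize_histogram(rnd)
  lut <- tapply(as.vector(eq2), as.vector(rnd), unique)
  expect_true(all(lengths(lut) == 1))
  expect_false(is.unsorted(unlist(lut)))
  expect_true(all(eq2 >= 0 & eq2 <= 255))
})

test_that("histogram equalization is idempotent up to one quantization level", {
  set.seed(13)
  for (i in 1:5) {
    img <- matrix(sample.int(256, 1024, replace = TRUE) - 1L, 32, 32)
    once <- equalize_histogram(img)
    twice <- equalize_histogram(once)
    expect_lte(max(abs(twice - once)), 1L)
  }
  ph <- flat_phantom(2)$image
  expect_lte(max(abs(equalize_histogram(equalize_histogram(ph)) -
                       equalize_histogram(ph))), 1L)
})

test_that("ROAD statistic matches closed forms and is a rank-ordered quantity", {
  expect_true(all(road_measure(matrix(50L, 7, 7)) == 0L))
  img <- matrix(0L, 3, 3); img[2, 2] <- 255L
  expect_identical(road_measure(img, k = 4)[2, 2], 1020L)  # 4 * 255
  # invariant to permuting the neighbour positions
  set.seed(4)
  nb <- sample.int(200, 8)
  m1 <- matrix(c(nb[1:4], 100L, nb[5:8]), 3, 3)
  m2 <- matrix(c(sample(nb), 100L)[c(1:4, 9, 5:8)], 3, 3)
  expect_identical(road_measure(m1)[2, 2], road_measure(m2)[2, 2])
})

test_that("the detector flags impulses and nothing else on clean images", {
  expect_false(any(detect_noise(matrix(128L, 16, 16))))
  img <- matrix(128L, 16, 16); img[7, 9] <- 255L
  det <- detect_noise(img)
  expect_identical(which(det), which(img == 255L))
  expect_identical(sum(det), 1L)
})

test_that("detection on a noisy texture-free phantom has high recall and low false-positive rate", {
  ph <- flat_phantom(7)
  nz <- add_impulse_noise(ph$image, noise_spec(0.3, "fixed", 42))
  det <- detect_noise(nz$image)
  recall <- sum(det & nz$mask) / sum(nz$mask)
  fpr <- sum(det & !nz$mask) / sum(!nz$mask)
  expect_gte(recall, 0.95)
  expect_lte(fpr, 0.05)
})

test_that("center-weighted median reduces to the expected order statistics", {
  expect_identical(center_weighted_median(1:9, 5L, 3L), 5L)
  set.seed(6)
  v <- sample.int(100, 7)
  expect_identical(center_weighted_median(v, v[4], 1L), sort(v)[4])
  expect_identical(center_weighted_median(1:9, 7L, 21L), 7L)  # weight dominates
  expect_error(center_weighted_median(integer(0), 5L), class = "otoseg_domain_error")
  expect_error(center_weighted_median(1:5, 3L, 2L), class = "otoseg_domain_error")
})

test_that("ACWM restores a single impulse in a constant image exactly", {
  img <- matrix(128L, 256, 256); img[100, 200] <- 255L
  f <- acwm_filter(img)
  expect_identical(f$image, matrix(128L, 256, 256))
  expect_identical(sum(f$mask), 1L)
  expect_true(f$mask[100, 200])
  expect_identical(f$fallbacks, 0L)
})

test_that("ACWM passes a clean texture-free phantom through untouched", {
  ph <- flat_phantom(5)
  f <- acwm_filter(ph$image)
  expect_false(any(f$mask))
  expect_identical(f$image, ph$image)
  expect_identical(f$equalized, equalize_histogram(ph$image))
})

test_that("ACWM never modifies unflagged pixels and lifts PSNR by at least 5 dB at p = 0.3", {
  ph <- flat_phantom(9)
  nz <- add_impulse_noise(ph$image, noise_spec(0.3, "fixed", 17))
  f <- acwm_filter(nz$image)
  expect_true(all(f$image[!f$mask] == nz$image[!f$mask]))
  expect_gt(psnr(ph$image, f$image), psnr(ph$image, nz$image) + 5)
})

test_that("weighted median filter matches a brute-force oracle and classic special cases", {
  expect_identical(weighted_median_filter(matrix(42L, 9, 9)), matrix(42L, 9, 9))
  set.seed(12)
  toy <- matrix(sample.int(256, 25) - 1L, 5, 5)
  cross <- matrix(0L, 3, 3)
  cross[2, ] <- 1L; cross[, 2] <- 1L; cross[2, 2] <- 3L
  expect_identical(weighted_median_filter(toy, weights = cross),
                   wm_bruteforce(toy, cross))
  ones <- matrix(1L, 3, 3)
  expect_identical(weighted_median_filter(toy, weights = ones),
                   wm_bruteforce(toy, ones))
  expect_error(weighted_median_filter(toy, window = 4L),
               class = "otoseg_domain_error")
  expect_error(weighted_median_filter(toy, weights = matrix(-1L, 3, 3)),
               class = "otoseg_domain_error")
})

test_that("adaptive median restores impulses and leaves rail-free content alone", {
  img <- matrix(128L, 64, 64); img[10, 10] <- 0L
  expect_identical(adaptive_median_filter(img), matrix(128L, 64, 64))
  # ramp: only pixels at the rails (its extreme ends) may change
  ramp <- matrix(rep(0:255, each = 4), 4, 256)
  storage.mode(ramp) <- "integer"
  am <- adaptive_median_filter(ramp)
  changed <- which(am != ramp, arr.ind = TRUE)
  expect_true(all(ramp[changed] %in% c(0L, 255L)))
  expect_true(all(changed[, 2] %in% c(1L, 256L)))
})

test_that("adaptive median exactly restores a constant image from 50% salt-and-pepper in the interior", {
  img <- matrix(128L, 128, 128)
  nz <- add_impulse_noise(img, noise_spec(0.5, "fixed", 33))$image
  am <- adaptive_median_filter(nz, max_window = 9L)
  interior <- am[5:124, 5:124]
  expect_true(all(interior == 128L))
})

test_that("all filters keep outputs inside the gray range on noisy phantoms", {
  ph <- make_phantom(phantom_spec(texture_sd = 3, rng_seed = 10))
  nz <- add_impulse_noise(ph$image, noise_spec(0.4, "fixed", 2))$image
  for (out in list(weighted_median_filter(nz), adaptive_median_filter(nz),
                   acwm_filter(nz)$image)) {
    expect_true(all(out >= 0L & out <= 255L))
  }
})

test_that("detecting on the equalized image inflates the false-positive rate on textured phantoms", {
  ph <- make_phantom(phantom_spec(membrane_band = c(210, 230),
                                  background_band = c(20, 40), cone = NULL,
                                  texture_sd = 3, rng_seed = 105L))
  nz <- add_impulse_noise(ph$image, noise_spec(0.3, "fixed", 5))
  clean <- !nz$mask
  fpr_raw <- sum(detect_noise(nz$image) & clean) / sum(clean)
  fpr_eq <- sum(detect_noise(equalize_histogram(nz$image)) & clean) / sum(clean)
  expect_lt(fpr_raw, 0.15)
  expect_gt(fpr_eq, 0.5)
  expect_gt(fpr_eq, 3 * fpr_raw)
})
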