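test_that("a texture-free two-class phantom is exactly two constant regions aligned with its truth", {
  ph <- make_phantom(phantom_spec(cone = NULL, effusion = NULL,
                                  texture_sd = 0, rng_seed = 1))
  expect_setequal(unique(as.vector(ph$image)), c(40L, 215L))
  expect_true(all((ph$image == 215L) == (ph$truth == 1L)))
  expect_true(all((ph$image == 40L) == (ph$truth == 0L)))
})

test_that("phantom generation is a pure function of spec and seed", {
  sp <- phantom_spec(texture_sd = 3, rng_seed = 11)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  # a different seed changes the texture realization
  c <- make_phantom(phantom_spec(texture_sd = 3, rng_seed = 12))
  expect_false(identical(a$image, c$image))
})

test_that("membrane pixel fraction matches the analytic ellipse area within rasterization error", {
  ph <- make_phantom(phantom_spec(rng_seed = 7))
  frac <- mean(ph$truth >= 1)
  analytic <- pi * 80 * 62 / (256 * 256)
  expect_lt(abs(frac - analytic) / analytic, 0.02)
})

test_that("phantom geometry outside the image bounds is a configuration error", {
  expect_error(phantom_spec(center = c(30.5, 128.5)), class = "otoseg_config_error")
  expect_error(phantom_spec(membrane_band = c(60, 80),
                            background_band = c(40, 60)),
               class = "otoseg_config_error")
})

test_that("an effusion blob appears as label 2 with shifted intensity", {
  sp <- phantom_spec(effusion = list(center = c(140.5, 140.5),
                                     axes = c(30, 22), shift = -35),
                     cone = NULL, rng_seed = 2)
  ph <- make_phantom(sp)
  expect_setequal(unique(as.vector(ph$truth)), c(0L, 1L, 2L))
  expect_true(all(ph$image[ph$truth == 2L] == 180L))
})

test_that("Otsu's threshold on a texture-free phantom recovers the ground truth exactly", {
  ph <- flat_phantom(3)
  thr <- EBImage::otsu(EBImage::Image(ph$image / 255)) * 255
  expect_identical((ph$image > thr) * 1L, ph$truth * 1L)
})

test_that("impulse injection corrupts exactly round(p * n) distinct pixels and marks them", {
  ph <- flat_phantom(7)
  nz <- add_impulse_noise(ph$image, noise_spec(0.3, "fixed", 42))
  expect_identical(sum(nz$mask), 19661L)  # round(0.3 * 65536)
  expect_true(all(nz$image[!nz$mask] == ph$image[!nz$mask]))
  expect_true(all(nz$image[nz$mask] %in% c(0L, 255L)))
  # measure-exact for a sweep of densities and sizes
  img <- matrix(100L, 13, 17)
  for (p in c(0.01, 0.25, 0.5, 0.99)) {
    m <- add_impulse_noise(img, noise_spec(p, "fixed", 1))$mask
    expect_identical(sum(m), as.integer(round(p * 221)))
  }
})

test_that("p = 0 leaves the image untouched and p = 1 puts every pixel on the rails", {
  img <- matrix(77L, 16, 16)
  z <- add_impulse_noise(img, noise_spec(0, "fixed", 5))
  expect_identical(z$image, img)
  expect_false(any(z$mask))
  o <- add_impulse_noise(img, noise_spec(1, "fixed", 5))
  expect_true(all(o$image %in% c(0L, 255L)))
  expect_true(all(o$mask))
})

test_that("random-valued impulses never equal the original pixel value", {
  img <- matrix(128L, 32, 32)
  z <- add_impulse_noise(img, noise_spec(0.5, "random", 9))
  expect_true(all(z$image[z$mask] != 128L))
  expect_true(all(z$image >= 0L & z$image <= 255L))
  # deterministic under the seed
  z2 <- add_impulse_noise(img, noise_spec(0.5, "random", 9))
  expect_identical(z$image, z2$image)
  expect_error(noise_spec(1.2), class = "otoseg_domain_error")
})

test_that("seeds fall inside their class interiors, one batch per class, deterministically", {
  ph <- flat_phantom(4)
  s <- make_seeds(ph$truth, per_class = 1L, rng_seed = 3)
  expect_identical(sum(s != 255L), 2L)
  s5 <- make_seeds(ph$truth, per_class = 5L, rng_seed = 3)
  idx <- which(s5 != 255L)
  expect_identical(length(idx), 10L)
  expect_true(all(s5[idx] == ph$truth[idx]))
  # >= 2 px from the class boundary: a 3x3 patch around each seed stays in class
  for (i in idx) {
    r <- (i - 1) %% 256 + 1; c <- (i - 1) %/% 256 + 1
    patch <- ph$truth[(r - 1):(r + 1), (c - 1):(c + 1)]
    expect_true(all(patch == ph$truth[r, c]))
  }
  expect_identical(s5, make_seeds(ph$truth, per_class = 5L, rng_seed = 3))
  expect_false(identical(s5, make_seeds(ph$truth, per_class = 5L, rng_seed = 4)))
})

test_that("seeding a class with too few pixels names the class in the error", {
  truth <- matrix(0L, 4, 4); truth[1, 1] <- 1L
  expect_error(make_seeds(truth, per_class = 2L, rng_seed = 1),
               "class 1", class = "otoseg_config_error")
})
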