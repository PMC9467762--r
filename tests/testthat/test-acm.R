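test_that("smoothed Heaviside has the atan form's symmetry and limits", {
  expect_equal(heaviside(0, 1.5), 0.5)
  z <- seq(-10, 10, by = 0.37)
  expect_equal(heaviside(z, 2) + heaviside(-z, 2), rep(1, length(z)))
  expect_false(is.unsorted(heaviside(z, 1)))
  eps <- 0.5
  expect_lt(abs(heaviside(10 * eps, eps) - 1), 0.07)
  expect_lt(abs(heaviside(-10 * eps, eps) - 0), 0.07)
  expect_error(heaviside(1, 0), class = "otoseg_domain_error")
})

test_that("template transform: identity is exact, integer translations shift exactly", {
  phi <- disc_sdf(c(33, 33), c(17, 17), 8)
  expect_equal(transform_template(phi, 0, 0, 1, 0), phi)
  sh <- transform_template(phi, 3, -2, 1, 0)
  # interior away from the fill border matches the shifted field
  expect_equal(sh[5:28, 8:30], disc_sdf(c(33, 33), c(20, 15), 8)[5:28, 8:30])
})

test_that("rotating a centered disc SDF changes nothing beyond interpolation error", {
  phi <- disc_sdf(c(41, 41), c(21, 21), 10)
  # quarter turns map the grid onto itself: exact
  expect_equal(transform_template(phi, 0, 0, 1, pi / 2), phi,
               tolerance = 1e-12)
  # a generic angle: inside the inscribed disc (where rotated sample
  # points stay on the grid) the error is bounded by bilinear
  # interpolation of the radial field, largest near the center cusp
  rot <- transform_template(phi, 0, 0, 1, 0.53)
  r <- sqrt(outer((1:41 - 21)^2, (1:41 - 21)^2, "+"))
  inside <- r < 15
  expect_lt(max(abs(rot - phi)[inside]), 0.3)
  expect_lt(max(abs(rot - phi)[inside & r > 3]), 0.05)
})

test_that("scaling a disc SDF rescales its zero level set", {
  phi <- disc_sdf(c(81, 81), c(41, 41), 15)
  grown <- transform_template(phi, 0, 0, 1.5, 0)
  area <- sum(grown >= 0)
  expect_lt(abs(area - pi * 22.5^2) / (pi * 22.5^2), 0.05)
  expect_error(transform_template(phi, 0, 0, -1, 0),
               class = "otoseg_domain_error")
})

test_that("shape energy vanishes on a match and adds areas for disjoint shapes", {
  phi_t <- disc_sdf(c(64, 64), c(32.5, 32.5), 10)
  expect_equal(shape_energy(phi_t, phi_t), 0, tolerance = 1e-12)
  a <- disc_sdf(c(64, 64), c(16.5, 16.5), 6)
  b <- disc_sdf(c(64, 64), c(48.5, 48.5), 8)
  e <- shape_energy(a, b, eps = 0.05)
  expect_lt(abs(e - (pi * 36 + pi * 64)) / (pi * 36 + pi * 64), 0.06)
  expect_gte(shape_energy(a, b), 0)
})

test_that("edge energy equals a naive double-loop evaluation", {
  set.seed(19)
  img <- matrix(sample.int(256, 64) - 1L, 8, 8)
  phi <- matrix(rnorm(64), 8, 8)
  eps <- 1.5
  I <- img / 255
  H <- heaviside(phi, eps)
  gx <- function(f, r, c) (f[r, min(c + 1, 8)] - f[r, max(c - 1, 1)]) / 2
  gy <- function(f, r, c) (f[min(r + 1, 8), c] - f[max(r - 1, 1), c]) / 2
  acc <- 0
  for (r in 1:8) for (c in 1:8)
    acc <- acc + (gx(H, r, c) - gx(I, r, c))^2 + (gy(H, r, c) - gy(I, r, c))^2
  expect_equal(edge_energy(phi, img, eps), acc, tolerance = 1e-12)
  # a flat image with a far-from-crossing flat phi has ~zero edge energy
  expect_lt(edge_energy(matrix(30, 16, 16), matrix(120L, 16, 16)), 1e-12)
})

test_that("Chan-Vese descent segments a texture-free disc from an enclosing circle", {
  img <- matrix(50L, 128, 128)
  truth_sdf <- disc_sdf(c(128, 128), c(64.5, 64.5), 30)
  img[truth_sdf >= 0] <- 200L
  init <- disc_sdf(c(128, 128), c(64.5, 64.5), 50) >= 0
  res <- acm_segment(img, init)
  expect_gte(dice_coef(res$labels, (truth_sdf >= 0) * 1L), 0.95)
  expect_true(all(diff(res$energy_trace) <= 1e-9))
  expect_true(all(res$labels %in% c(0L, 1L)))  # binary-partition-complete
})

test_that("an initialization already on the true boundary is immediately stable", {
  img <- matrix(50L, 64, 64)
  d <- disc_sdf(c(64, 64), c(32.5, 32.5), 18)
  img[d >= 0] <- 200L
  res <- acm_segment(img, d >= 0)
  expect_lte(res$iterations, 10L)
  expect_gte(dice_coef(res$labels, (d >= 0) * 1L), 0.99)
})

test_that("a dominant shape prior pulls the contour onto the best-fit transformed template", {
  img <- matrix(50L, 96, 96)
  d <- disc_sdf(c(96, 96), c(52.5, 46.5), 20)   # off-center disc
  img[d >= 0] <- 180L
  tpl <- disc_sdf(c(96, 96), c(48.5, 48.5), 20) # centered template
  init <- disc_sdf(c(96, 96), c(48.5, 48.5), 32) >= 0
  res <- acm_segment(img, init, phi_template = tpl,
                     weights = c(0.05, 10, 0), max_iters = 120L)
  # oracle: exhaustive small grid search over the similarity pose space
  best <- NULL; best_iou <- -1
  for (tx in -6:6) for (ty in -6:6) for (s in c(0.9, 1, 1.1, 1.2)) {
    m <- transform_template(tpl, tx, ty, s, 0) >= 0
    iou <- sum(m & res$labels == 1L) / sum(m | res$labels == 1L)
    if (iou > best_iou) { best_iou <- iou; best <- c(tx, ty, s) }
  }
  fit <- (transform_template(tpl, best[1], best[2], best[3], 0) >= 0) * 1L
  expect_gte(dice_coef(res$labels, fit), 0.95)
})

test_that("acm input contracts are enforced", {
  img <- matrix(100L, 32, 32)
  expect_error(acm_segment(img, matrix(FALSE, 32, 32)),
               class = "otoseg_domain_error")
  expect_error(acm_segment(img, matrix(TRUE, 32, 32), weights = c(0, 1, 0)),
               class = "otoseg_domain_error")  # w2 > 0 without template
  expect_error(acm_segment(img, matrix(TRUE, 16, 16)),
               class = "otoseg_domain_error")
})
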