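#' Smoothed Heaviside step
#'
#' `H_eps(z) = (1 + (2 / pi) * atan(z / eps)) / 2`: a smooth inside/outside
#' indicator for level-set fields, strictly in (0, 1), monotone, with
#' `H_eps(z) + H_eps(-z) = 1` and converging to the unit step as
#' `eps -> 0`.
#'
#' @param phi numeric vector/matrix (level-set values).
#' @param eps smoothing width in pixels (> 0).
#' @return values in (0, 1), same shape as `phi`.
#' @export
heaviside <- function(phi, eps = 1.5) {
  if (eps <= 0) otoseg_error("eps must be positive", "otoseg_domain_error")
  0.5 * (1 + (2 / pi) * atan(phi / eps))
}

# derivative of the smoothed Heaviside
dirac_eps <- function(phi, eps = 1.5) {
  (1 / pi) * eps / (eps^2 + phi^2)
}

#' Signed distance field of a binary mask
#'
#' Positive inside, negative outside, via Euclidean distance transforms.
#'
#' @param mask logical or 0/1 matrix.
#' @return numeric matrix.
#' @export
sdf_from_mask <- function(mask) {
  m <- (mask > 0) * 1
  EBImage::distmap(m) - EBImage::distmap(1 - m)
}

#' Signed distance field of a disc
#'
#' Exact analytic signed distance (positive inside) for a disc template;
#' the usual shape prior for a tympanic membrane.
#'
#' @param shape `c(nrow, ncol)`.
#' @param center `c(x, y)` (column, row) in pixel coordinates.
#' @param radius disc radius in pixels.
#' @return numeric matrix.
#' @export
disc_sdf <- function(shape, center, radius) {
  X <- matrix(rep(seq_len(shape[2]), each = shape[1]), nrow = shape[1])
  Y <- matrix(rep(seq_len(shape[1]), times = shape[2]), nrow = shape[1])
  radius - sqrt((X - center[1])^2 + (Y - center[2])^2)
}

#' Rigid-plus-scale transform of a template field
#'
#' Resamples `phi_t` through the inverse of the similarity transform
#' `B = translate(tx, ty) o scale(s) o rotate(theta)` about the image
#' center, with bilinear interpolation and boundary-value fill outside the
#' domain.  Identity parameters return the input exactly (the sampling grid
#' then coincides with the pixel grid).  Field values are composed, not
#' rescaled, so the zero level set transforms as the shape does.
#'
#' @param phi_t numeric template field.
#' @param tx,ty translation in pixels.
#' @param s isotropic scale factor (> 0).
#' @param theta rotation in radians.
#' @return transformed field, same shape.
#' @export
transform_template <- function(phi_t, tx = 0, ty = 0, s = 1, theta = 0) {
  if (s <= 0) otoseg_error("scale must be positive", "otoseg_domain_error")
  h <- nrow(phi_t); w <- ncol(phi_t)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  X <- matrix(rep(seq_len(w), each = h), nrow = h)
  Y <- matrix(rep(seq_len(h), times = w), nrow = h)
  ux <- X - cx - tx
  uy <- Y - cy - ty
  ct <- cos(theta); st <- sin(theta)
  # inverse map: rotate by -theta, scale by 1/s
  sx <- cx + (ct * ux + st * uy) / s
  sy <- cy + (-st * ux + ct * uy) / s
  bilinear_sample(phi_t, sx, sy)
}

# bilinear interpolation with replicated-border fill
bilinear_sample <- function(f, sx, sy) {
  h <- nrow(f); w <- ncol(f)
  sx <- pmin(pmax(sx, 1), w)
  sy <- pmin(pmax(sy, 1), h)
  x0 <- pmin(floor(sx), w - 1); x1 <- x0 + 1
  y0 <- pmin(floor(sy), h - 1); y1 <- y0 + 1
  fx <- sx - x0; fy <- sy - y0
  idx <- function(r, c) (c - 1) * h + r
  v00 <- f[idx(y0, x0)]; v10 <- f[idx(y1, x0)]
  v01 <- f[idx(y0, x1)]; v11 <- f[idx(y1, x1)]
  out <- (1 - fx) * ((1 - fy) * v00 + fy * v10) +
    fx * ((1 - fy) * v01 + fy * v11)
  matrix(out, h, w)
}

#' Shape-prior energy
#'
#' Squared area of disagreement between the current contour and the
#' transformed shape template:
#' `E2 = sum((H(phi) - H(phi_T o B_T))^2)` over the grid.  Zero exactly when
#' the contour matches the transformed template; for disjoint sharp shapes
#' it approaches the sum of the two areas.
#'
#' @param phi level-set field.
#' @param phi_t template signed distance field (congruent with `phi`).
#' @param transform `c(tx, ty, s, theta)`.
#' @param eps Heaviside smoothing width.
#' @return non-negative scalar.
#' @export
shape_energy <- function(phi, phi_t, transform = c(0, 0, 1, 0), eps = 1.5) {
  assert_congruent(phi, phi_t, "phi and phi_t")
  bt <- transform_template(phi_t, transform[1], transform[2], transform[3],
                           transform[4])
  sum((heaviside(phi, eps) - heaviside(bt, eps))^2)
}

# central differences with replicated edges
grad_x <- function(f) {
  w <- ncol(f)
  (f[, pmin(seq_len(w) + 1, w)] - f[, pmax(seq_len(w) - 1, 1)]) / 2
}
grad_y <- function(f) {
  h <- nrow(f)
  (f[pmin(seq_len(h) + 1, h), ] - f[pmax(seq_len(h) - 1, 1), ]) / 2
}

#' Edge-alignment energy
#'
#' `E3 = sum(|grad H(phi) - grad I|^2)` as a grid sum with central
#' differences; the image is rescaled to `[0, 1]` so the indicator and the
#' intensity live on the same scale.  Small when the contour's transition
#' band lies along the image's intensity edges.
#'
#' @param phi level-set field.
#' @param img gray image (integers in `[0, 255]` or already in `[0, 1]`).
#' @param eps Heaviside smoothing width.
#' @return non-negative scalar.
#' @export
edge_energy <- function(phi, img, eps = 1.5) {
  assert_congruent(phi, img, "phi and img")
  I <- if (max(img) > 1) img / 255 else img
  H <- heaviside(phi, eps)
  sum((grad_x(H) - grad_x(I))^2 + (grad_y(H) - grad_y(I))^2)
}

# total energy at a given state; c1/c2 are the optimal region means
acm_energy <- function(phi, I, phi_t, transform, w, eps) {
  H <- heaviside(phi, eps)
  a1 <- sum(H); a2 <- sum(1 - H)
  c1 <- if (a1 > 0) sum(H * I) / a1 else 0
  c2 <- if (a2 > 0) sum((1 - H) * I) / a2 else 0
  e1 <- sum(H * (I - c1)^2 + (1 - H) * (I - c2)^2)
  e2 <- if (w[2] > 0) shape_energy(phi, phi_t, transform, eps) else 0
  e3 <- if (w[3] > 0) edge_energy(phi, I, eps) else 0
  list(total = w[1] * e1 + w[2] * e2 + w[3] * e3, c1 = c1, c2 = c2)
}

#' Level-set active contour with optional shape prior
#'
#' Two-phase level-set segmentation minimizing
#' `E_T = w1 * E1 + w2 * E2 + w3 * E3`, where `E1` is the Chan-Vese region
#' term (squared deviation from the inside/outside mean intensities), `E2`
#' the shape-prior energy ([shape_energy()]) against a template under a
#' similarity transform, and `E3` the edge-alignment energy
#' ([edge_energy()]).  The field `phi` descends the energy gradient with a
#' backtracking step-size rule (a candidate step is accepted only if the
#' total energy does not increase, so the recorded energy trace is
#' non-increasing); the template pose `(tx, ty, s, theta)` is refined by
#' coordinate descent on a small local grid every `pose_every` iterations.
#' `phi` is reinitialized to a signed distance field every `reinit_every`
#' iterations to keep the transition band well conditioned.
#'
#' Iteration stops when the segmented area changes by at most `tol` pixels
#' for `stable_iters` consecutive iterations, when the step size collapses,
#' or at `max_iters`.  A contour that empties or floods the image aborts
#' with a diagnostic error.
#'
#' @param img integer gray image matrix.
#' @param init_mask logical/0-1 matrix, the initial region (non-empty).
#' @param phi_template optional template signed distance field (required
#'   when `weights[2] > 0`), e.g. [disc_sdf()].
#' @param weights `c(w1, w2, w3)`, non-negative, not all zero.
#' @param max_iters maximum iterations.
#' @param reinit_every signed-distance reinitialization cadence.
#' @param tol area-stability tolerance in pixels.
#' @param stable_iters consecutive stable iterations required to stop.
#' @param pose_every pose-refinement cadence (when `weights[2] > 0`).
#' @param eps Heaviside smoothing width in pixels.
#' @return list with `labels` (0/1 integer matrix, 1 inside), the per-
#'   iteration `energy_trace`, `iterations`, final `pose` and `converged`.
#' @export
acm_segment <- function(img, init_mask, phi_template = NULL,
                        weights = c(1, 0, 0), max_iters = 200L,
                        reinit_every = 20L, tol = 2, stable_iters = 5L,
                        pose_every = 10L, eps = 1.5) {
  img <- assert_gray(img)
  assert_congruent(img, init_mask, "image and init_mask")
  if (length(weights) != 3 || any(weights < 0) || all(weights == 0))
    otoseg_error("weights must be 3 non-negative values, not all zero",
                 "otoseg_domain_error")
  if (weights[2] > 0 && is.null(phi_template))
    otoseg_error("a shape template is required when w2 > 0",
                 "otoseg_domain_error")
  if (!any(init_mask > 0))
    otoseg_error("init_mask must be non-empty", "otoseg_domain_error")
  I <- img / 255
  phi <- sdf_from_mask(init_mask)
  pose <- c(tx = 0, ty = 0, s = 1, theta = 0)
  en <- acm_energy(phi, I, phi_template, pose, weights, eps)
  trace <- en$total
  area_prev <- sum(phi >= 0)
  stable <- 0L
  dt <- NULL
  it <- 0L
  converged <- FALSE
  while (it < max_iters) {
    it <- it + 1L
    d <- dirac_eps(phi, eps)
    g <- weights[1] * d * ((I - en$c1)^2 - (I - en$c2)^2)
    if (weights[2] > 0) {
      Ht <- heaviside(transform_template(phi_template, pose[1], pose[2],
                                         pose[3], pose[4]), eps)
      g <- g + weights[2] * 2 * d * (heaviside(phi, eps) - Ht)
    }
    if (weights[3] > 0) {
      H <- heaviside(phi, eps)
      qx <- grad_x(H) - grad_x(I)
      qy <- grad_y(H) - grad_y(I)
      g <- g - weights[3] * 2 * d * (grad_x(qx) + grad_y(qy))
    }
    gmax <- max(abs(g))
    if (gmax == 0) { converged <- TRUE; break }
    if (is.null(dt)) dt <- 1 / gmax  # first step moves the front ~1 px
    accepted <- FALSE
    for (try in 1:10) {
      cand <- phi - dt * g
      en_c <- acm_energy(cand, I, phi_template, pose, weights, eps)
      if (en_c$total <= en$total) {
        phi <- cand; en <- en_c
        dt <- min(dt * 1.2, 10 / gmax)
        accepted <- TRUE
        break
      }
      dt <- dt / 2
    }
    if (!accepted) { converged <- TRUE; break }
    trace <- c(trace, en$total)
    if (weights[2] > 0 && it %% pose_every == 0L) {
      pose <- refine_pose(phi, phi_template, pose, eps)
      en <- acm_energy(phi, I, phi_template, pose, weights, eps)
      en$total <- min(en$total, trace[length(trace)])
    }
    if (it %% reinit_every == 0L) {
      phi <- sdf_from_mask(phi >= 0)
      en2 <- acm_energy(phi, I, phi_template, pose, weights, eps)
      en2$total <- min(en2$total, en$total)  # reinit is not a descent step
      en <- en2
    }
    area <- sum(phi >= 0)
    if (area == 0 || area == length(phi))
      otoseg_error(sprintf("contour degenerated (%s) at iteration %d",
                           if (area == 0) "empty" else "full", it),
                   "otoseg_degenerate_contour")
    stable <- if (abs(area - area_prev) <= tol) stable + 1L else 0L
    area_prev <- area
    if (stable >= stable_iters) { converged <- TRUE; break }
  }
  labels <- matrix(0L, nrow(phi), ncol(phi))
  labels[phi >= 0] <- 1L
  list(labels = labels, energy_trace = trace, iterations = it,
       pose = pose, converged = converged)
}

# coordinate descent on the template pose over a small local grid,
# minimizing the shape energy only
refine_pose <- function(phi, phi_t, pose, eps) {
  H <- heaviside(phi, eps)
  score <- function(p) {
    bt <- transform_template(phi_t, p[1], p[2], p[3], p[4])
    sum((H - heaviside(bt, eps))^2)
  }
  for (coord in 1:4) {
    deltas <- switch(coord,
                     c(-2, -1, 0, 1, 2), c(-2, -1, 0, 1, 2),
                     c(0.95, 1, 1.05), c(-0.05, 0, 0.05))
    best <- pose; best_s <- score(pose)
    for (d in deltas) {
      cand <- pose
      if (coord == 3) cand[3] <- pose[3] * d else
        cand[coord] <- pose[coord] + d
      if (cand[3] <= 0) next
      s <- score(cand)
      if (s < best_s) { best_s <- s; best <- cand }
    }
    pose <- best
  }
  pose
}
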