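#' Pixel neighbourhoods
#'
#' In-bounds neighbours of a pixel under the Von Neumann (4-connected,
#' L1 distance 1) or Moore (8-connected, L-infinity distance 1)
#' neighbourhood.
#'
#' @param p pixel as `c(row, col)` (1-based).
#' @param kind `"vonneumann"` or `"moore"`.
#' @param shape image dimensions `c(nrow, ncol)`.
#' @return integer matrix with one `(row, col)` neighbour per row.
#' @export
neighbors <- function(p, kind = c("vonneumann", "moore"), shape) {
  kind <- match.arg(kind)
  if (p[1] < 1 || p[1] > shape[1] || p[2] < 1 || p[2] > shape[2])
    otoseg_error("pixel lies outside the image", "otoseg_domain_error")
  if (kind == "vonneumann") {
    off <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
    off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  }
  q <- cbind(p[1] + off[, 1], p[2] + off[, 2])
  keep <- q[, 1] >= 1 & q[, 1] <= shape[1] & q[, 2] >= 1 & q[, 2] <= shape[2]
  q <- q[keep, , drop = FALSE]
  dimnames(q) <- list(NULL, c("row", "col"))
  q
}

#' GrowCut cellular-automaton segmentation
#'
#' Seeded segmentation by the GrowCut automaton.  Each cell carries a state
#' triplet (label, strength, feature): seeds start with strength 1,
#' unlabeled cells with strength 0, and the feature is the pixel gray level.
#' In every synchronous sweep each labeled neighbour `q` attacks `p` with
#' `g(|C_p - C_q|) * theta_q`, `g(d) = 1 - d / 255`; `p` adopts the
#' strongest attacker's label when the attack strictly exceeds its own
#' strength.  Equal attacks are resolved toward the smaller label, so the
#' evolution is fully deterministic.  Iteration stops when a sweep changes
#' neither labels nor strengths (the state is then a fixed point) or after
#' `max_iters` sweeps.
#'
#' Strengths never decrease, and because `g <= 1` a region boundary with
#' full feature contrast (difference 255) is impassable - which is exactly
#' the behaviour wanted from seeds placed inside the membrane and the canal
#' background.
#'
#' @param img integer gray image matrix (the feature map).
#' @param seeds integer seed label map; `unlabeled` marks unseeded cells,
#'   all other values are class labels (label 0 is allowed, e.g. for
#'   background).
#' @param kind neighbourhood, `"moore"` (default) or `"vonneumann"`.
#' @param max_iters maximum number of sweeps (>= 1).
#' @param unlabeled sentinel used in `seeds` for unseeded cells.
#' @return list with `labels` (integer matrix; unreached cells keep the
#'   sentinel), `strengths`, `iterations` and `converged`.
#' @export
growcut_segment <- function(img, seeds, kind = c("moore", "vonneumann"),
                            max_iters = 2000L, unlabeled = 255L) {
  kind <- match.arg(kind)
  img <- assert_gray(img)
  assert_congruent(img, seeds, "image and seeds")
  max_iters <- as.integer(max_iters)
  if (max_iters < 1L)
    otoseg_error("max_iters must be >= 1", "otoseg_domain_error")
  seeded <- seeds != unlabeled
  if (!any(seeded))
    otoseg_error("seeds must contain at least one labeled pixel",
                 "otoseg_domain_error")
  # internal coding: 0 = unlabeled, class labels shifted up by 1
  lab0 <- matrix(0L, nrow(img), ncol(img))
  lab0[seeded] <- as.integer(seeds[seeded]) + 1L
  th0 <- matrix(0, nrow(img), ncol(img))
  th0[seeded] <- 1
  res <- growcut_cpp(img, lab0, th0, kind == "moore", max_iters)
  if (!res$converged)
    warning("GrowCut did not converge within max_iters sweeps")
  labels <- res$labels
  out <- matrix(as.integer(unlabeled), nrow(img), ncol(img))
  reached <- labels != 0L
  out[reached] <- labels[reached] - 1L
  list(labels = out, strengths = res$strengths,
       iterations = res$iterations, converged = res$converged)
}
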