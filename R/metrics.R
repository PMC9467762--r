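#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10((L - 1)^2 / MSE)` in dB, with the mean squared error
#' taken over all pixels (borders included) and peak `L - 1 = 255` by
#' default.  Identical images have zero MSE and return `Inf`.
#'
#' @param reference,test congruent integer gray image matrices.
#' @param L number of gray levels.
#' @return PSNR in dB (`Inf` when the images are identical).
#' @export
psnr <- function(reference, test, L = 256L) {
  assert_congruent(reference, test, "reference and test images")
  mse <- mean((as.numeric(reference) - as.numeric(test))^2)
  if (mse == 0) return(Inf)
  10 * log10((L - 1)^2 / mse)
}

# contingency table of two congruent label maps
label_contingency <- function(s1, s2) {
  assert_congruent(s1, s2, "label maps")
  table(factor(as.vector(s1)), factor(as.vector(s2)))
}

#' Rand index of two segmentations
#'
#' Fraction of unordered pixel pairs on which the two labelings agree
#' (both co-clustered or both separated), in `[0, 1]`, invariant to label
#' permutation, and 1 exactly for identical partitions.  Computed from the
#' label contingency table, which is algebraically identical to enumerating
#' all `n (n - 1) / 2` pixel pairs.
#'
#' @param s1,s2 congruent label map matrices.
#' @return value in `[0, 1]`.
#' @export
rand_index <- function(s1, s2) {
  n <- length(s1)
  if (n < 2) otoseg_error("need at least 2 pixels", "otoseg_domain_error")
  tab <- label_contingency(s1, s2)
  pairs <- function(x) sum(x * (x - 1) / 2)
  total <- n * (n - 1) / 2
  both_same <- pairs(tab)
  same1 <- pairs(rowSums(tab))
  same2 <- pairs(colSums(tab))
  (total + 2 * both_same - same1 - same2) / total
}

#' Global consistency error
#'
#' Region-overlap error tolerant to mutual refinement: with the local
#' refinement error `E(Sa, Sb, p) = |R(Sa, p) \ R(Sb, p)| / |R(Sa, p)|`
#' (regions taken as label classes),
#' `GCE = min(sum_p E(S1, S2, p), sum_p E(S2, S1, p)) / n`.  Zero when one
#' segmentation refines the other; at most 1.
#'
#' @param s1,s2 congruent label map matrices.
#' @return value in `[0, 1]`.
#' @export
gce <- function(s1, s2) {
  n <- length(s1)
  if (n == 0) otoseg_error("label maps are empty", "otoseg_domain_error")
  tab <- label_contingency(s1, s2)
  r1 <- rowSums(tab)
  r2 <- colSums(tab)
  e12 <- sum(tab * (r1[row(tab)] - tab) / r1[row(tab)])
  e21 <- sum(tab * (r2[col(tab)] - tab) / r2[col(tab)])
  min(e12, e21) / n
}

#' Variation of information
#'
#' Information-theoretic distance between two labelings:
#' `VI = H(S1) + H(S2) - 2 I(S1; S2)` in bits, computed from the joint
#' pixel-label distribution.  Zero iff the partitions coincide; bounded by
#' `log2(n)`; a true metric (symmetric, triangle inequality).
#'
#' @param s1,s2 congruent label map matrices.
#' @return non-negative value in bits.
#' @export
variation_of_information <- function(s1, s2) {
  n <- length(s1)
  if (n == 0) otoseg_error("label maps are empty", "otoseg_domain_error")
  tab <- label_contingency(s1, s2) / n
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h1 <- ent(rowSums(tab))
  h2 <- ent(colSums(tab))
  hj <- ent(as.vector(tab))
  mi <- h1 + h2 - hj
  max(h1 + h2 - 2 * mi, 0)
}

#' Score a segmentation against a reference
#'
#' Convenience wrapper computing the three partition metrics used by the
#' segmentation benchmark.
#'
#' @param pred,truth congruent label map matrices.
#' @return list with `ri`, `gce` and `vi`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  list(ri = rand_index(pred, truth), gce = gce(pred, truth),
       vi = variation_of_information(pred, truth))
}
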