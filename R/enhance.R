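#' Gray-level histogram of an 8-bit image
#'
#' Counts pixels at each gray level `i` in `[0, L - 1]`; the level
#' probabilities `p(i) = n_i / n` and their cumulative distribution are the
#' derived views used by [equalize_histogram()].
#'
#' @param img integer gray image matrix.
#' @param L number of gray levels.
#' @return object of class `gray_histogram`: list with `counts` (length `L`),
#'   `n`, and `L`.
#' @export
gray_histogram <- function(img, L = 256L) {
  img <- assert_gray(img, L)
  counts <- tabulate(as.vector(img) + 1L, nbins = L)
  structure(list(counts = counts, n = length(img), L = as.integer(L)),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  occ <- which(x$counts > 0) - 1L
  cat(sprintf("gray_histogram: n = %d, L = %d, %d occupied levels (%d..%d)\n",
              x$n, x$L, length(occ), min(occ), max(occ)))
  invisible(x)
}

#' Histogram equalization
#'
#' Monotone gray remapping through the intensity CDF that flattens the
#' histogram: `y = round((L - 1) * (CDF(v) - cdf_min) / (n - cdf_min))`,
#' where `cdf_min` is the CDF at the lowest occupied level.  Constant images
#' are returned unchanged (the mapping is degenerate there), so no division
#' by zero can occur.  The mapping is non-decreasing in the input level and
#' idempotent up to one gray level of quantization.
#'
#' @inheritParams gray_histogram
#' @return equalized integer image matrix.
#' @export
equalize_histogram <- function(img, L = 256L) {
  img <- assert_gray(img, L)
  h <- tabulate(as.vector(img) + 1L, nbins = L)
  occ <- which(h > 0)
  if (length(occ) <= 1L) return(img)
  n <- length(img)
  cdf <- cumsum(h)
  cmin <- cdf[occ[1]]
  lut <- as.integer(round((L - 1) * (cdf - cmin) / (n - cmin)))
  lut[lut < 0L] <- 0L
  out <- matrix(lut[img + 1L], nrow(img), ncol(img))
  storage.mode(out) <- "integer"
  out
}

#' Configuration of the HE/ACWM filter
#'
#' Tunables of the adaptive center-weighted median filter: the noise
#' detector combines a rank-ordered absolute difference (ROAD) statistic
#' with a fixed-valued extreme test on a window that grows adaptively with
#' the local density of extreme pixels.
#'
#' @param base_window,max_window odd window sizes (pixels) bounding the
#'   adaptive window.
#' @param center_weight odd positive center weight of the replacement
#'   median.
#' @param road_k number of smallest neighbour differences summed by the
#'   ROAD statistic (of the 8 Moore neighbours).
#' @param road_threshold gray-level threshold above which the ROAD
#'   statistic flags a pixel.
#' @param window_growth_fraction fraction of window pixels at the window
#'   extremes that triggers growth of the detection window.
#' @return object of class `acwm_config`.
#' @export
acwm_config <- function(base_window = 3L, max_window = 9L,
                        center_weight = 3L, road_k = 4L,
                        road_threshold = 40, window_growth_fraction = 0.5) {
  if (!is_odd(base_window) || !is_odd(max_window) || base_window < 3L ||
      base_window > max_window)
    otoseg_error("windows must be odd with 3 <= base_window <= max_window",
                 "otoseg_config_error")
  if (!is_odd(center_weight) || center_weight < 1L)
    otoseg_error("center_weight must be an odd positive integer",
                 "otoseg_config_error")
  if (road_k < 1L || road_k > 8L)
    otoseg_error("road_k must be in 1..8", "otoseg_config_error")
  structure(list(base_window = as.integer(base_window),
                 max_window = as.integer(max_window),
                 center_weight = as.integer(center_weight),
                 road_k = as.integer(road_k),
                 road_threshold = as.numeric(road_threshold),
                 window_growth_fraction = as.numeric(window_growth_fraction)),
            class = "acwm_config")
}

#' Rank-ordered absolute difference (ROAD) statistic
#'
#' For every pixel, the sum of the `k` smallest absolute differences between
#' the pixel and its 8 Moore neighbours (replicated-edge padding at the
#' borders).  Impulses sit far from most of their neighbours and score high;
#' edge pixels keep a same-region majority and score low, which is what makes
#' ROAD a sharper impulse detector than a plain local range.
#'
#' @param img integer gray image matrix.
#' @param k number of smallest differences summed (`<= 8`).
#' @return integer matrix of ROAD values.
#' @export
road_measure <- function(img, k = 4L) {
  img <- assert_gray(img)
  k <- as.integer(k)
  if (k < 1L || k > 8L)
    otoseg_error("k must be in 1..8", "otoseg_domain_error")
  road_map_cpp(img, k)
}

#' Detect impulse-corrupted pixels
#'
#' A pixel is flagged when its ROAD statistic exceeds `road_threshold`, or
#' when it equals the minimum or maximum of its adaptive window while the
#' window median lies strictly between the window extremes (the classic
#' fixed-valued impulse test).  The window starts at `base_window` and grows
#' by 2 up to `max_window` while the fraction of window pixels sitting at
#' the window extremes exceeds `window_growth_fraction`, so clustered noise
#' still gets judged against a clean majority.  Deterministic.
#'
#' @param img integer gray image matrix.
#' @param cfg an [acwm_config()].
#' @return logical matrix marking flagged pixels.
#' @export
detect_noise <- function(img, cfg = acwm_config()) {
  img <- assert_gray(img)
  detect_noise_cpp(img, cfg$base_window, cfg$max_window, cfg$road_k,
                   cfg$road_threshold, cfg$window_growth_fraction)
}

#' Center-weighted median of a multiset
#'
#' Median of the multiset formed by `values` with `center_value` counted
#' `weight` times in total (the center is assumed present once in `values`,
#' so `weight - 1` extra copies are added).  With `weight = 1` this is the
#' ordinary median; a weight exceeding twice the multiset size returns the
#' center value itself.  Even-sized multisets take the lower median for
#' determinism.
#'
#' @param values numeric vector of gray levels (non-empty).
#' @param center_value the center sample.
#' @param weight odd positive integer.
#' @return gray level.
#' @export
center_weighted_median <- function(values, center_value, weight = 3L) {
  if (length(values) == 0)
    otoseg_error("`values` must be non-empty", "otoseg_domain_error")
  if (!is_odd(weight) || weight < 1L)
    otoseg_error("weight must be an odd positive integer",
                 "otoseg_domain_error")
  m <- sort(c(values, rep(center_value, weight - 1L)))
  m[ceiling(length(m) / 2)]
}

#' HE/ACWM switching impulse-noise filter
#'
#' The five-phase filter: (1) histogram equalization of the input exposes
#' impulses by stretching local contrast; (2) adaptive-window noise
#' detection ([detect_noise()]) on the equalized image; (3)-(5) replacement
#' of each flagged pixel by the center-weighted median of the non-flagged
#' pixels of its window, grown until at least 3 non-flagged pixels are
#' available or `max_window` is reached, with the center weight applied to
#' the nearest non-flagged pixel.  Non-flagged pixels pass through
#' unchanged, which is what makes this a switching filter: clean detail is
#' never smoothed.
#'
#' With `output = "original"` (the default) the filter maps values back to
#' the input's intensity range: replacement medians are taken over the
#' non-flagged pixels of the *input* image and unflagged pixels keep their
#' input values, so the result is directly comparable to the clean
#' original.  `output = "equalized"` keeps the whole result in the
#' equalized domain (replacements and pass-through from the equalized
#' image), in which case the natural reference for quality metrics is the
#' equalized clean image.
#'
#' Windows exhausted with zero non-flagged pixels fall back to the plain
#' median of the full maximum window; the number of such fallbacks is
#' reported.
#'
#' @param img integer gray image matrix.
#' @param cfg an [acwm_config()].
#' @param output `"original"` (map back to the input range) or
#'   `"equalized"`.
#' @param detect_on domain the detector runs in.  `road_threshold` is a
#'   raw gray-scale quantity, so the default detects on the original
#'   intensities; `"equalized"` runs the detector on the contrast-
#'   stretched image instead (which inflates the false-positive rate on
#'   textured images, since equalization amplifies within-region contrast
#'   past a fixed threshold).
#' @return list with `image` (filtered), `equalized` (the equalized
#'   input), `mask` (the detection mask used) and `fallbacks` (count of
#'   exhausted-window fallbacks).
#' @export
acwm_filter <- function(img, cfg = acwm_config(),
                        output = c("original", "equalized"),
                        detect_on = c("original", "equalized")) {
  img <- assert_gray(img)
  output <- match.arg(output)
  detect_on <- match.arg(detect_on)
  eq <- equalize_histogram(img)
  mask <- detect_noise(if (detect_on == "original") img else eq, cfg)
  carrier <- if (output == "original") img else eq
  rep <- acwm_replace_cpp(carrier, mask, cfg$base_window, cfg$max_window,
                          cfg$center_weight)
  list(image = rep$image, equalized = eq, mask = mask,
       fallbacks = rep$fallbacks)
}

#' Sliding weighted median filter (baseline)
#'
#' Every pixel is replaced by the weighted median of its window under a
#' non-negative integer weight stencil, applied uniformly (no switching).
#' The default stencil is the classic 3x3 center-weight-3 median.
#'
#' @param img integer gray image matrix.
#' @param window odd window size; ignored when `weights` is given.
#' @param weights odd square integer matrix of non-negative weights.
#' @return filtered integer image matrix.
#' @export
weighted_median_filter <- function(img, window = 3L, weights = NULL) {
  img <- assert_gray(img)
  if (is.null(weights)) {
    if (!is_odd(window) || window < 3L)
      otoseg_error("window must be odd and >= 3", "otoseg_domain_error")
    weights <- matrix(1L, window, window)
    weights[(window + 1L) / 2L, (window + 1L) / 2L] <- 3L
  }
  if (!is.matrix(weights) || nrow(weights) != ncol(weights) ||
      !is_odd(nrow(weights)))
    otoseg_error("weights must be an odd square matrix",
                 "otoseg_domain_error")
  if (any(weights < 0) || any(weights != round(weights)) ||
      sum(weights) < 1)
    otoseg_error("weights must be non-negative integers with positive sum",
                 "otoseg_domain_error")
  storage.mode(weights) <- "integer"
  weighted_median_cpp(img, weights)
}

#' Adaptive median filter (baseline)
#'
#' Two-stage adaptive median for impulse noise: stage A grows the window
#' from 3x3 by 2 while the window median is an extreme gray level (0 or
#' `L - 1`, the values fixed-valued impulses take); stage B replaces the
#' pixel only if the pixel itself is such an extreme, otherwise it passes
#' through untouched.  At the maximum window size the window median is
#' output as a best effort.  Pixels whose value is not an impulse extreme
#' are therefore never altered, and images free of extreme values pass
#' through unchanged.
#'
#' @param img integer gray image matrix.
#' @param max_window odd maximum window size (>= 3).
#' @param L number of gray levels.
#' @return filtered integer image matrix.
#' @export
adaptive_median_filter <- function(img, max_window = 9L, L = 256L) {
  img <- assert_gray(img, L)
  if (!is_odd(max_window) || max_window < 3L)
    otoseg_error("max_window must be odd and >= 3", "otoseg_domain_error")
  adaptive_median_cpp(img, as.integer(max_window), as.integer(L))
}
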