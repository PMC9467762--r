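# Orthonormal Haar analysis/synthesis and the multiscale histogram
# threshold segmenter built on it.

haar_pair <- function(v) {
  # v has even length; returns list(approx, detail), orthonormal kernels
  a <- v[seq(1, length(v), by = 2)]
  b <- v[seq(2, length(v), by = 2)]
  list(s = (a + b) / sqrt(2), d = (a - b) / sqrt(2))
}

haar_cols <- function(m) {
  odd <- m[seq(1, nrow(m), by = 2), , drop = FALSE]
  even <- m[seq(2, nrow(m), by = 2), , drop = FALSE]
  list(s = (odd + even) / sqrt(2), d = (odd - even) / sqrt(2))
}

haar_rows <- function(m) {
  odd <- m[, seq(1, ncol(m), by = 2), drop = FALSE]
  even <- m[, seq(2, ncol(m), by = 2), drop = FALSE]
  list(s = (odd + even) / sqrt(2), d = (odd - even) / sqrt(2))
}

interleave_cols <- function(s, d) {
  out <- matrix(0, 2 * nrow(s), ncol(s))
  out[seq(1, nrow(out), by = 2), ] <- (s + d) / sqrt(2)
  out[seq(2, nrow(out), by = 2), ] <- (s - d) / sqrt(2)
  out
}

interleave_rows <- function(s, d) {
  out <- matrix(0, nrow(s), 2 * ncol(s))
  out[, seq(1, ncol(out), by = 2)] <- (s + d) / sqrt(2)
  out[, seq(2, ncol(out), by = 2)] <- (s - d) / sqrt(2)
  out
}

#' 2-D orthonormal Haar wavelet analysis
#'
#' Decomposes an image into `levels` subband quadruples (LL, LH, HL, HH):
#' LL is the coarse approximation, LH/HL carry horizontal/vertical detail
#' and HH diagonal detail.  The transform is orthonormal, so
#' [idwt2()] reconstructs exactly (to numerical precision) and total
#' coefficient energy equals pixel energy (Parseval).
#'
#' @param img numeric or integer image matrix; both dimensions must be
#'   divisible by `2^levels`.
#' @param levels number of decomposition levels (>= 1).
#' @return object of class `wavelet_pyramid`: list with `levels` (each a
#'   list `LL`, `LH`, `HL`, `HH`; only the final level's `LL` is needed for
#'   synthesis but every level stores its own) and `wavelet = "haar"`.
#' @export
dwt2 <- function(img, levels = 1L) {
  if (!is.matrix(img)) otoseg_error("`img` must be a matrix",
                                    "otoseg_domain_error")
  levels <- as.integer(levels)
  if (levels < 1L) otoseg_error("levels must be >= 1", "otoseg_domain_error")
  if (nrow(img) %% 2^levels != 0 || ncol(img) %% 2^levels != 0)
    otoseg_error(sprintf(
      "image dimensions %dx%d not divisible by 2^%d: too many levels",
      nrow(img), ncol(img), levels), "otoseg_domain_error")
  cur <- img * 1.0
  out <- vector("list", levels)
  for (j in seq_len(levels)) {
    rw <- haar_rows(cur)        # low/high along x
    cl <- haar_cols(rw$s)       # then along y
    ch <- haar_cols(rw$d)
    out[[j]] <- list(LL = cl$s, LH = ch$s, HL = cl$d, HH = ch$d)
    cur <- cl$s
  }
  structure(list(levels = out, wavelet = "haar"),
            class = "wavelet_pyramid")
}

#' 2-D orthonormal Haar wavelet synthesis
#'
#' Inverse of [dwt2()]: reconstructs the image from a wavelet pyramid.
#'
#' @param pyr a `wavelet_pyramid` from [dwt2()].
#' @return numeric image matrix.
#' @export
idwt2 <- function(pyr) {
  if (!inherits(pyr, "wavelet_pyramid"))
    otoseg_error("`pyr` must be a wavelet_pyramid", "otoseg_domain_error")
  n <- length(pyr$levels)
  cur <- pyr$levels[[n]]$LL
  for (j in rev(seq_len(n))) {
    lv <- pyr$levels[[j]]
    lo <- interleave_cols(cur, lv$HL)
    hi <- interleave_cols(lv$LH, lv$HH)
    cur <- interleave_rows(lo, hi)
  }
  cur
}

# 1-D Haar approximation pyramid of a vector (list of approximations,
# level 0 = the vector itself)
haar_approx_pyramid <- function(v, levels) {
  out <- vector("list", levels + 1)
  out[[1]] <- v
  for (j in seq_len(levels)) {
    v <- haar_pair(v)$s
    out[[j + 1]] <- v
  }
  out
}

# local maxima of a vector (strictly greater than both neighbours;
# one-sided at the ends)
local_maxima <- function(a) {
  n <- length(a)
  if (n < 2) return(integer(0))
  left <- c(-Inf, a[-n])
  right <- c(a[-1], -Inf)
  which(a > left & a > right)
}

#' Multiscale wavelet histogram threshold segmentation
#'
#' Binary segmentation by thresholding, with the threshold located on a
#' Haar approximation pyramid of the 256-bin gray histogram: at the
#' coarsest scale (chosen so the approximation keeps at least 8 bins) the
#' deepest interior minimum between the two largest histogram maxima gives
#' a rough threshold, which is then mapped back scale by scale (bin index
#' doubling per level) and refined within a +/-2-bin corridor against the
#' approximation at each finer scale.  Coarse-to-fine search makes the
#' threshold robust to histogram noise while still landing in the true
#' valley.  Ties inside a corridor resolve toward the corridor center,
#' then toward the smaller bin.  A histogram that is unimodal at the
#' coarsest scale falls back to the histogram median with a warning.
#'
#' @param img integer gray image matrix with at least 2 occupied levels.
#' @param levels pyramid depth; `NULL` picks the deepest level whose
#'   approximation keeps >= 8 bins (5 for 256 gray levels).
#' @param n_classes only 2 is supported.
#' @param L number of gray levels.
#' @return list with `labels` (0/1 integer matrix, 1 above threshold) and
#'   `threshold` (gray level; pixels `> threshold` are labeled 1).
#' @export
dwt_threshold_segment <- function(img, levels = NULL, n_classes = 2L,
                                  L = 256L) {
  img <- assert_gray(img, L)
  if (n_classes != 2L)
    otoseg_error("only two-class thresholding is supported",
                 "otoseg_domain_error")
  h <- tabulate(as.vector(img) + 1L, nbins = L)
  if (sum(h > 0) < 2L)
    otoseg_error("image must have at least 2 occupied gray levels",
                 "otoseg_domain_error")
  max_levels <- floor(log2(L / 8))
  levels <- if (is.null(levels)) max_levels else min(as.integer(levels),
                                                     max_levels)
  levels <- max(levels, 1L)
  pyr <- haar_approx_pyramid(as.numeric(h), levels)
  coarse <- pyr[[levels + 1]]
  mx <- local_maxima(coarse)
  thr_bin <- NULL
  if (length(mx) >= 2) {
    top2 <- mx[order(coarse[mx], decreasing = TRUE)[1:2]]
    p1 <- min(top2); p2 <- max(top2)
    if (p2 - p1 >= 2) {
      interior <- (p1 + 1):(p2 - 1)
      vals <- coarse[interior]
      cand <- interior[vals == min(vals)]
      mid <- (p1 + p2) / 2
      thr_bin <- cand[order(abs(cand - mid), cand)][1]
    }
  }
  if (is.null(thr_bin)) {
    warning("histogram unimodal at the coarsest scale; falling back to the histogram median")
    thr <- which(cumsum(h) >= length(img) / 2)[1] - 1L
  } else {
    # map back level by level, refining inside a +/-2-bin corridor
    for (j in rev(seq_len(levels))) {
      a <- pyr[[j]]
      center <- 2 * thr_bin - 0.5
      cand <- (2 * thr_bin - 3):(2 * thr_bin + 2)
      cand <- cand[cand >= 1 & cand <= length(a)]
      vals <- a[cand]
      best <- cand[vals == min(vals)]
      thr_bin <- best[order(abs(best - center), best)][1]
    }
    thr <- thr_bin - 1L  # 1-based bin index -> gray level
  }
  labels <- matrix(0L, nrow(img), ncol(img))
  labels[img > thr] <- 1L
  list(labels = labels, threshold = as.integer(thr))
}
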