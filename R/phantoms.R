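#' Specify a synthetic tympanic-membrane phantom
#'
#' Describes a seeded synthetic otoscope-style test image: a bright elliptical
#' membrane on a dark canal background, an optional "cone of light" wedge
#' (the bright reflex seen on a healthy eardrum) and an optional darker
#' effusion blob, plus additive Gaussian texture.  Phantoms stand in for
#' clinical otoscope images so that every downstream stage (denoising,
#' segmentation, evaluation) is testable against a known ground truth.
#'
#' Intensity bands must be separated by at least 30 gray levels so the
#' membrane/background classes stay separable.  Centers default to
#' half-integer coordinates so that the rasterized ellipse has no
#' single-pixel staircase tips: every boundary pixel then keeps a same-class
#' majority in its 3x3 neighbourhood, a property smooth anatomy shares and
#' one that median-type filters rely on to leave clean edges untouched.
#'
#' @param width,height image size in pixels.
#' @param center ellipse center `c(x, y)` in pixel coordinates (column, row).
#' @param axes ellipse semi-axes `c(ax, ay)` in pixels.
#' @param membrane_band,background_band two-element gray-level bands
#'   `c(lo, hi)`; region base intensity is the band midpoint.
#' @param cone `NULL`, or a list with `direction_deg` (0 = +x, 90 = down the
#'   image), `half_angle_deg`, `radius_frac` (fraction of the elliptical
#'   radius) and `boost` (gray-level increment).
#' @param effusion `NULL`, or a list with `center`, `axes` and `shift`
#'   (gray-level increment, usually negative) describing a fluid blob.
#' @param texture_sd standard deviation (gray levels) of additive Gaussian
#'   texture; 0 gives piecewise-constant regions.
#' @param rng_seed integer seed; identical spec and seed give bit-identical
#'   phantoms.
#' @return an object of class `phantom_spec`.
#' @seealso [make_phantom()], [phantom_suite()]
#' @export
phantom_spec <- function(width = 256L, height = 256L,
                         center = c(128.5, 128.5), axes = c(80, 62),
                         membrane_band = c(205, 225),
                         background_band = c(30, 50),
                         cone = list(direction_deg = 90, half_angle_deg = 15,
                                     radius_frac = 0.85, boost = 30),
                         effusion = NULL, texture_sd = 0, rng_seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               center = as.numeric(center), axes = as.numeric(axes),
               membrane_band = as.numeric(membrane_band),
               background_band = as.numeric(background_band),
               cone = cone, effusion = effusion,
               texture_sd = as.numeric(texture_sd),
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  w <- spec$width; h <- spec$height
  if (w < 8L || h < 8L)
    otoseg_error("phantom image must be at least 8x8", "otoseg_config_error")
  cx <- spec$center[1]; cy <- spec$center[2]
  ax <- spec$axes[1]; ay <- spec$axes[2]
  if (ax <= 0 || ay <= 0)
    otoseg_error("ellipse axes must be positive", "otoseg_config_error")
  if (cx - ax < 1 || cx + ax > w || cy - ay < 1 || cy + ay > h)
    otoseg_error("membrane ellipse extends outside the image bounds",
                 "otoseg_config_error")
  bands_ok <- function(b) length(b) == 2 && all(b >= 0) && all(b <= 255) &&
    b[1] <= b[2]
  if (!bands_ok(spec$membrane_band) || !bands_ok(spec$background_band))
    otoseg_error("intensity bands must be c(lo, hi) within [0, 255]",
                 "otoseg_config_error")
  if (min(spec$membrane_band) - max(spec$background_band) < 30)
    otoseg_error("membrane and background bands must be separated by >= 30 gray levels",
                 "otoseg_config_error")
  if (!is.null(spec$effusion)) {
    e <- spec$effusion
    if (e$center[1] - e$axes[1] < 1 || e$center[1] + e$axes[1] > w ||
        e$center[2] - e$axes[2] < 1 || e$center[2] + e$axes[2] > h)
      otoseg_error("effusion ellipse extends outside the image bounds",
                   "otoseg_config_error")
  }
  if (spec$texture_sd < 0)
    otoseg_error("texture_sd must be non-negative", "otoseg_config_error")
  spec
}

#' Generate a phantom image and its ground-truth label map
#'
#' Rasterizes a [phantom_spec()] into an 8-bit grayscale image and an aligned
#' label map with labels 0 (background), 1 (membrane) and 2 (effusion, when
#' present).  The cone-of-light wedge is an intensity feature of the membrane
#' and does not get its own label.  Pure function of `(spec, rng_seed)`.
#'
#' @param spec a [phantom_spec()].
#' @return list with integer matrices `image` and `truth`.
#' @examples
#' ph <- make_phantom(phantom_spec(cone = NULL, rng_seed = 7))
#' table(ph$truth)
#' @export
make_phantom <- function(spec) {
  spec <- validate_phantom_spec(spec)
  w <- spec$width; h <- spec$height
  X <- matrix(rep(seq_len(w), each = h), nrow = h)
  Y <- matrix(rep(seq_len(h), times = w), nrow = h)
  cx <- spec$center[1]; cy <- spec$center[2]
  ax <- spec$axes[1]; ay <- spec$axes[2]
  er2 <- ((X - cx) / ax)^2 + ((Y - cy) / ay)^2
  inside <- er2 <= 1
  bg <- round(mean(spec$background_band))
  mem <- round(mean(spec$membrane_band))
  img <- matrix(bg, h, w)
  img[inside] <- mem
  truth <- matrix(0L, h, w)
  truth[inside] <- 1L
  if (!is.null(spec$cone)) {
    cn <- spec$cone
    ang <- atan2(Y - cy, X - cx) * 180 / pi
    adiff <- ((ang - cn$direction_deg + 180) %% 360) - 180
    wedge <- inside & abs(adiff) <= cn$half_angle_deg &
      sqrt(er2) <= cn$radius_frac
    # clamp to [1, 254]: legitimate phantom content stays off the impulse
    # rails 0/255, so fixed-valued corruption always changes a pixel
    img[wedge] <- pmin(254, img[wedge] + cn$boost)
  }
  if (!is.null(spec$effusion)) {
    e <- spec$effusion
    eb <- ((X - e$center[1]) / e$axes[1])^2 +
      ((Y - e$center[2]) / e$axes[2])^2 <= 1
    eb <- eb & inside
    img[eb] <- pmin(254, pmax(1, img[eb] + e$shift))
    truth[eb] <- 2L
  }
  if (spec$texture_sd > 0) {
    img <- local_seed(spec$rng_seed,
                      img + round(rnorm(length(img), 0, spec$texture_sd)))
    img <- pmin(pmax(img, 1), 254)
  }
  storage.mode(img) <- "integer"
  list(image = img, truth = truth)
}

#' Specify an impulse-noise corruption
#'
#' @param density fraction `p` of pixels to corrupt, in `[0, 1]`.
#' @param kind `"fixed"` for salt-and-pepper (values 0 and `L - 1`) or
#'   `"random"` for random-valued impulses drawn uniformly over
#'   `[0, L - 1]` excluding the pixel's original value.
#' @param rng_seed integer seed.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(density, kind = c("fixed", "random"), rng_seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(density) || length(density) != 1 ||
      density < 0 || density > 1)
    otoseg_error("noise density must be a single value in [0, 1]",
                 "otoseg_domain_error")
  structure(list(density = as.numeric(density), kind = kind,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

#' Inject impulse noise at an exact pixel count
#'
#' Corrupts exactly `round(p * n)` distinct pixels (sampled without
#' replacement) so tests can assert exact counts; the returned mask marks
#' exactly the corrupted pixels and all other pixels are unchanged.
#' Random-valued impulses never equal the original pixel value, so every
#' masked pixel is genuinely corrupted.
#'
#' @param img integer gray image matrix.
#' @param noise a [noise_spec()].
#' @param L number of gray levels.
#' @return list with `image` (corrupted copy) and `mask` (logical matrix).
#' @export
add_impulse_noise <- function(img, noise, L = 256L) {
  img <- assert_gray(img, L)
  if (!inherits(noise, "noise_spec"))
    otoseg_error("`noise` must be a noise_spec", "otoseg_domain_error")
  n <- length(img)
  m <- round(noise$density * n)
  mask <- matrix(FALSE, nrow(img), ncol(img))
  if (m == 0) return(list(image = img, mask = mask))
  local_seed(noise$rng_seed, {
    idx <- sample.int(n, m)
    if (noise$kind == "fixed") {
      img[idx] <- sample(c(0L, L - 1L), m, replace = TRUE)
    } else {
      u <- sample.int(L - 1L, m, replace = TRUE) - 1L  # 0 .. L-2
      img[idx] <- u + (u >= img[idx])                  # skip original value
    }
  })
  mask[idx] <- TRUE
  list(image = img, mask = mask)
}

#' Draw seed pixels from the interior of each ground-truth class
#'
#' Produces a sparse seed label map (for [growcut_segment()]) with
#' `per_class` pixels per class, drawn at least 2 px from the class boundary
#' when enough interior exists, and the `unlabeled` sentinel elsewhere.
#' Label 0 is a legitimate class (background), hence the sentinel default
#' of 255, which round-trips through 8-bit PNG.
#'
#' @param truth integer label map.
#' @param per_class number of seeds per class (>= 1).
#' @param rng_seed integer seed.
#' @param unlabeled sentinel value for unseeded pixels.
#' @return integer matrix of seeds.
#' @export
make_seeds <- function(truth, per_class = 1L, rng_seed = 1L,
                       unlabeled = 255L) {
  if (!is.matrix(truth)) otoseg_error("`truth` must be a matrix",
                                      "otoseg_domain_error")
  per_class <- as.integer(per_class)
  if (per_class < 1L)
    otoseg_error("per_class must be >= 1", "otoseg_domain_error")
  classes <- sort(unique(as.integer(truth)))
  if (unlabeled %in% classes)
    otoseg_error("unlabeled sentinel collides with a class label",
                 "otoseg_domain_error")
  seeds <- matrix(as.integer(unlabeled), nrow(truth), ncol(truth))
  local_seed(rng_seed, {
    for (cl in classes) {
      inclass <- truth == cl
      if (sum(inclass) < per_class)
        otoseg_error(sprintf("class %d has %d pixels, too few for %d seeds",
                             cl, sum(inclass), per_class),
                     "otoseg_config_error")
      dist <- EBImage::distmap(inclass * 1)
      interior <- which(dist >= 2)
      if (length(interior) < per_class) interior <- which(inclass)
      pick <- interior[sample.int(length(interior), per_class)]
      seeds[pick] <- cl
    }
  })
  seeds
}
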