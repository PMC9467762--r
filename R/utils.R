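# Internal helpers shared across modules.

otoseg_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "otoseg_error")))
}

#' @noRd
assert_gray <- function(img, L = 256L, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    otoseg_error(sprintf("`%s` must be a numeric matrix", arg),
                 "otoseg_domain_error")
  if (nrow(img) < 1L || ncol(img) < 1L)
    otoseg_error(sprintf("`%s` must have at least one pixel", arg),
                 "otoseg_domain_error")
  if (anyNA(img) || any(img < 0) || any(img > L - 1) ||
      any(img != round(img)))
    otoseg_error(sprintf("`%s` must hold integers in [0, %d]", arg, L - 1L),
                 "otoseg_domain_error")
  storage.mode(img) <- "integer"
  img
}

#' @noRd
assert_congruent <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    otoseg_error(sprintf("%s must have identical dimensions", what),
                 "otoseg_domain_error")
  invisible(TRUE)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
#' @noRd
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
is_odd <- function(x) x %% 2 == 1
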