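# Image, table and config IO for the pipeline.

#' Read an 8-bit grayscale image
#'
#' Reads PNG (always available) or TIFF (when the tiff package is
#' installed) into an integer matrix in `[0, 255]`.  RGB(A) input is
#' converted to gray with the standard luminance weights.  Inputs with more
#' than 8 bits per sample are rejected.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @return integer gray image matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    otoseg_error(sprintf("cannot read image: no such file '%s'", path),
                 "otoseg_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      otoseg_error("the tiff package is required to read TIFF files",
                   "otoseg_io_error")
    x <- tiff::readTIFF(path)
  } else {
    otoseg_error(sprintf("unsupported image format '%s' for '%s'", ext, path),
                 "otoseg_io_error")
  }
  if (length(dim(x)) == 3) {
    nc <- dim(x)[3]
    x <- if (nc >= 3)
      0.2989 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    else x[, , 1]
  }
  v <- x * 255
  if (max(abs(v - round(v))) > 1e-6)
    otoseg_error(sprintf("'%s' is not an 8-bit image (unsupported depth)",
                         path), "otoseg_io_error")
  out <- round(v)
  storage.mode(out) <- "integer"
  out
}

#' Write an 8-bit grayscale image or label map as PNG
#'
#' Values in `[0, 255]` are written losslessly; `read_image(write_image(x))`
#' round-trips exactly.
#'
#' @param img integer matrix in `[0, 255]`.
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- assert_gray(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a benchmark table as CSV
#'
#' Fixed formatting ('.' decimal separator, 4 decimals, `Inf` written as
#' the string `"inf"`, UTF-8) so that identical runs produce byte-identical
#' files.
#'
#' @param df data frame.
#' @param path output path.
#' @param digits decimals for numeric columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, digits = 4L) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- out[[j]]
      s <- sprintf(paste0("%.", digits, "f"), v)
      s[is.infinite(v) & v > 0] <- "inf"
      s[is.infinite(v) & v < 0] <- "-inf"
      out[[j]] <- s
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a YAML configuration file
#'
#' @param path YAML file path.
#' @return named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    otoseg_error(sprintf("cannot read config: no such file '%s'", path),
                 "otoseg_io_error")
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    otoseg_error(sprintf("malformed YAML in '%s': %s", path,
                         conditionMessage(e)), "otoseg_io_error"))
  cfg
}
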