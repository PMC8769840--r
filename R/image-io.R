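#' Read an 8-bit RGB microscopy image
#'
#' Reads a PNG or TIFF blood-smear image into an `H x W x 3` numeric array
#' with intensities on the 0--255 scale (the scale all color references and
#' weight vectors in this package use). Grayscale files are replicated to
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG or TIFF file.
#' @return Numeric array of dimension `H x W x 3`, values in `[0, 255]`.
#' @export
read_rgb <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: '", ext, "' (PNG or TIFF expected)",
         call. = FALSE)
  )
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]
  validate_rgb(px * 255)
}

#' Write a binary mask as a single-channel PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Pixels with intensity above 0.5 (on the unit scale) are foreground.
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px > 0.5
}

#' Write an RGB array as PNG
#'
#' @param img `H x W x 3` array on the 0--255 scale.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  img <- validate_rgb(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Convert an RGB image to grayscale luminance
#'
#' Uses ITU-R 601 weights (0.299 R + 0.587 G + 0.114 B) and rescales to
#' `[0, 1]`, the range the SIFT scale space and the CNN operate on.
#'
#' @param img `H x W x 3` array (0--255) or an `H x W` matrix already in
#'   `[0, 1]` (returned unchanged).
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) {
    stopifnot(all(is.finite(img)))
    return(img)
  }
  img <- validate_rgb(img)
  (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]) / 255
}

# Checks the RGBImage contract: H x W x 3, finite, values in [0, 255].
validate_rgb <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  if (!all(is.finite(img))) stop("image contains non-finite values", call. = FALSE)
  if (min(img) < 0 || max(img) > 255) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  img
}
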