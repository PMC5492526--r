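#' Read an RGB image from disk
#'
#' Reads PNG/TIFF/JPEG/BMP via EBImage and returns the package's raster
#' carrier: a `width x height x 3` numeric array with values in `[0, 1]`.
#' Grayscale images are expanded to three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to an image file.
#' @return A `width x height x 3` numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  } else if (dim(a)[3L] > 3L) {
    a <- a[, , 1:3, drop = FALSE]
  } else if (dim(a)[3L] == 2L) {      # gray + alpha
    a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  }
  a <- pmin(pmax(a, 0), 1)
  storage.mode(a) <- "double"
  a
}

#' Write an RGB image or a binary mask as PNG
#'
#' @param image A `width x height x 3` array in `[0, 1]`, or a logical /
#'   numeric `width x height` matrix (written as grayscale).
#' @param path Output path; the format is inferred from the extension
#'   (PNG recommended).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (is.logical(image)) image <- image * 1
  x <- if (length(dim(image)) == 3L) {
    EBImage::Image(image, colormode = "Color")
  } else {
    EBImage::Image(image, colormode = "Grayscale")
  }
  EBImage::writeImage(x, path)
  invisible(path)
}

assert_color_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stopf("%s must be a width x height x 3 array", arg)
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stopf("%s must have values in [0, 1] and no NAs", arg)
  invisible(TRUE)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stopf("%s must be a logical matrix", arg)
  invisible(TRUE)
}
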