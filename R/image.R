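#' RGB trap images
#'
#' Images are plain numeric arrays of dimension `H x W x 3` holding
#' integer intensities in `[0, 255]`; the first index is the row (y),
#' the second the column (x). Helpers here validate that convention and
#' convert to and from the `EBImage` representation (x-major, `[0, 1]`).
#'
#' @param pixels An `H x W x 3` array in `[0, 255]`.
#' @return `rgb_image()` returns the validated array.
#' @export
rgb_image <- function(pixels) {
  validate_image(pixels)
  pixels
}

validate_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("invalid image: expected an H x W x 3 array")
  d <- dim(img)
  if (d[1] < 1L || d[2] < 1L) stop("invalid image: empty")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("invalid image: channel values must lie in [0, 255]")
  invisible(img)
}

#' @rdname rgb_image
#' @param value Scalar or length-3 colour used to fill the image.
#' @param height,width Image size in pixels.
#' @export
uniform_image <- function(height, width, value) {
  if (length(value) == 1L) value <- rep(value, 3L)
  rgb_image(array(rep(value, each = height * width), c(height, width, 3L)))
}

as_ebimage <- function(img) {
  EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

from_ebimage <- function(eb) {
  aperm(EBImage::imageData(eb), c(2L, 1L, 3L)) * 255
}

#' Read and write images
#'
#' `read_image()` loads a PNG or JPEG file into the package's
#' `H x W x 3` array convention; `write_image()` writes a PNG.
#'
#' @param path File path.
#' @return `read_image()` returns an image array; `write_image()`
#'   returns `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    x <- png::readPNG(path)
    if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
    if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
    return(rgb_image(round(x * 255)))
  }
  eb <- EBImage::readImage(path)
  x <- EBImage::imageData(eb)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  rgb_image(round(aperm(x, c(2L, 1L, 3L)) * 255))
}

#' @rdname read_image
#' @param img Image array.
#' @export
write_image <- function(img, path) {
  validate_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}
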