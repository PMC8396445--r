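#' Convert an RGB image to CIELAB planes
#'
#' Standard sRGB to CIELAB conversion (D65 white point), applied
#' per pixel. The luminance plane `L` ranges over `[0, 100]`; the two
#' colour-opponent planes `a` and `b` are roughly `[-128, 127]`.
#'
#' @param image An `H x W x 3` array in `[0, 255]` (see [rgb_image()]).
#' @return A list with matrices `L`, `a`, `b`, each `H x W`.
#' @examples
#' lab <- to_lab(uniform_image(4, 4, c(255, 255, 255)))
#' range(lab$L) # ~100 everywhere
#' @export
to_lab <- function(image) {
  validate_image(image)
  d <- dim(image)
  rgb <- cbind(as.vector(image[, , 1]),
               as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  lab <- farver::convert_colour(rgb, from = "rgb", to = "lab")
  list(L = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

# Normalized Gaussian kernel with radius ceiling(3 * sigma).
gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Gaussian smoothing of a plane
#'
#' Convolution with a normalized Gaussian kernel of radius
#' `ceiling(3 * sigma)`; image borders are handled by edge replication,
#' so a constant plane is returned unchanged.
#'
#' @param plane A numeric matrix.
#' @param sigma Kernel standard deviation in pixels; must be positive.
#' @return A matrix of the same shape as `plane`.
#' @export
gaussian_smooth <- function(plane, sigma) {
  if (!is.matrix(plane)) stop("plane must be a matrix")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive number")
  k <- gaussian_kernel(sigma)
  r <- (nrow(k) - 1L) / 2L
  # filter2 requires the filter to fit inside the image; pad small planes
  # by edge replication first so the contract holds for any plane size.
  h <- nrow(plane); w <- ncol(plane)
  if (h <= 2L * r || w <= 2L * r) {
    ri <- pmin(pmax(seq_len(h + 2L * r) - r, 1L), h)
    ci <- pmin(pmax(seq_len(w + 2L * r) - r, 1L), w)
    padded <- plane[ri, ci, drop = FALSE]
    out <- EBImage::filter2(padded, k, boundary = "replicate")
    return(out[(r + 1L):(r + h), (r + 1L):(r + w), drop = FALSE])
  }
  EBImage::filter2(plane, k, boundary = "replicate")
}

#' Frequency-tuned saliency map
#'
#' Each pixel's saliency is the Euclidean distance, in CIELAB space,
#' between the mean colour of the whole image and the Gaussian-blurred
#' colour at that pixel:
#' `S(r, c) = || mu - [L_blur(r,c), a_blur(r,c), b_blur(r,c)] ||_2`,
#' where `mu` holds the means of the unblurred `L`, `a`, `b` planes.
#' On a near-uniform trap background this is close to zero everywhere
#' except at insect blobs.
#'
#' @param image An `H x W x 3` array in `[0, 255]`.
#' @param sigma Blur standard deviation in pixels (default 3, chosen so
#'   that insects in the 10-40 px range survive the smoothing).
#' @return An `H x W` matrix of non-negative saliency scores, not yet
#'   normalized (see [normalize_saliency()]).
#' @examples
#' S <- compute_saliency(uniform_image(8, 8, c(230, 200, 40)))
#' max(S) # 0: a constant image has no salient structure
#' @export
compute_saliency <- function(image, sigma = 3) {
  lab <- to_lab(image)
  mu <- c(mean(lab$L), mean(lab$a), mean(lab$b))
  bl <- gaussian_smooth(lab$L, sigma)
  ba <- gaussian_smooth(lab$a, sigma)
  bb <- gaussian_smooth(lab$b, sigma)
  S <- sqrt((mu[1] - bl)^2 + (mu[2] - ba)^2 + (mu[3] - bb)^2)
  attr(S, "normalized") <- FALSE
  S
}

#' Rescale a saliency map to unit maximum
#'
#' Divides by the maximum score so thresholds are expressed on `[0, 1]`;
#' an identically-zero map is returned unchanged. Maps whose maximum is
#' below 1e-8 are treated as zero: a featureless image yields only
#' floating-point residue from the blur, and rescaling that residue
#' would fabricate structure out of rounding noise.
#'
#' @param S Saliency matrix with non-negative entries.
#' @return The rescaled matrix with attribute `normalized = TRUE`.
#' @export
normalize_saliency <- function(S) {
  if (!is.matrix(S) || min(S) < 0) stop("S must be a non-negative matrix")
  m <- max(S)
  if (m > 1e-8) S <- S / m else S[] <- 0
  attr(S, "normalized") <- TRUE
  S
}

#' Threshold a saliency map into a binary mask
#'
#' Pixels whose saliency is greater than or equal to `alpha` become 1,
#' all others 0. `alpha` is interpreted on the normalized `[0, 1]` scale
#' (default 0.10); lowering it grows the activation regions, raising it
#' shrinks them.
#'
#' @param S Saliency matrix (normalized; see [normalize_saliency()]).
#' @param alpha Threshold in `[0, 1]`.
#' @return An `H x W` integer matrix of 0/1 values.
#' @export
threshold_mask <- function(S, alpha = 0.10) {
  if (!is.matrix(S)) stop("S must be a matrix")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  M <- matrix(as.integer(S >= alpha), nrow(S), ncol(S))
  M
}

#' Export a saliency map for inspection
#'
#' Writes the normalized map either as a grayscale PNG or as a flat
#' CSV of scores.
#'
#' @param S Saliency matrix.
#' @param path Output file; format chosen by extension (.png or .csv).
#' @return `path`, invisibly.
#' @export
write_saliency <- function(S, path) {
  Sn <- normalize_saliency(S)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(Sn, path, dpi = NULL)
  } else {
    utils::write.table(Sn, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
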