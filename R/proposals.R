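#' Activation regions from a binary mask
#'
#' Groups the 1-pixels of a thresholded saliency mask into connected
#' components ("activation regions"). Each region carries its tight
#' bounding box (0-based, half-open), its pixel count, and the centroid
#' of its pixel centers.
#'
#' @param M Binary mask matrix of 0/1 values.
#' @param connectivity 4 or 8 (default 8, so that thin appendages such
#'   as insect legs stay attached to the body).
#' @return A data frame with one row per region, sorted by
#'   `(xmin, ymin)`: columns `xmin`, `ymin`, `xmax`, `ymax`,
#'   `pixel_count`, `xc`, `yc`.
#' @examples
#' M <- matrix(0L, 5, 5); M[2, 2] <- 1L; M[3, 3] <- 1L
#' nrow(connected_components(M, 8)) # 1: diagonal pixels touch
#' nrow(connected_components(M, 4)) # 2
#' @export
connected_components <- function(M, connectivity = 8) {
  if (!is.matrix(M) || !all(M %in% c(0L, 1L)))
    stop("M must be a 0/1 matrix")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  H <- nrow(M); W <- ncol(M)
  ones <- which(M == 1L)
  if (!length(ones)) return(empty_regions())

  r <- ((ones - 1L) %% H) + 1L
  c <- ((ones - 1L) %/% H) + 1L
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))

  from <- integer(0); to <- integer(0)
  for (off in offsets) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- M[nb] == 1L
    from <- c(from, ones[ok][hit])
    to <- c(to, nb[hit])
  }
  ids <- match(c(from, to), ones)
  g <- igraph::make_empty_graph(n = length(ones), directed = FALSE)
  if (length(ids))
    g <- igraph::add_edges(g, rbind(ids[seq_along(from)],
                                    ids[seq_along(to) + length(from)]))
  memb <- igraph::components(g)$membership

  # 0-based pixel coordinates; pixel (row, col) covers [col, col+1) x [row, row+1)
  x0 <- c - 1L; y0 <- r - 1L
  regions <- data.frame(
    xmin = as.integer(tapply(x0, memb, min)),
    ymin = as.integer(tapply(y0, memb, min)),
    xmax = as.integer(tapply(x0, memb, max)) + 1L,
    ymax = as.integer(tapply(y0, memb, max)) + 1L,
    pixel_count = as.integer(tapply(x0, memb, length)),
    xc = as.numeric(tapply(x0 + 0.5, memb, mean)),
    yc = as.numeric(tapply(y0 + 0.5, memb, mean))
  )
  regions <- regions[order(regions$xmin, regions$ymin), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

empty_regions <- function() {
  data.frame(xmin = integer(0), ymin = integer(0), xmax = integer(0),
             ymax = integer(0), pixel_count = integer(0),
             xc = numeric(0), yc = numeric(0))
}

#' Area filter for activation regions
#'
#' Discards regions whose bounding-box area falls below `beta` (px^2);
#' such components are usually small non-target species or residual
#' noise. Regions whose area equals `beta` survive.
#'
#' @param regions Data frame from [connected_components()].
#' @param beta Minimum box area in px^2 (default 30).
#' @return The surviving rows, order preserved.
#' @export
area_filter <- function(regions, beta = 30) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("beta must be a non-negative number")
  if (!nrow(regions)) return(regions)
  regions[box_area(regions) >= beta, , drop = FALSE]
}

#' Background/foreground gate against ground truth
#'
#' An activation region is foreground when it overlaps at least one
#' ground-truth box with `iogt >= iogt_threshold`; otherwise (including
#' when there are no ground truths at all) it is background. This is the
#' training-mode gate; at inference time the gate is a patch classifier.
#'
#' @param region One-row region data frame (needs `xmin..ymax`).
#' @param gts Ground-truth data frame with columns `xmin..ymax`, `label`.
#' @param iogt_threshold Threshold in `(0, 1]` (default 0.5).
#' @return `"foreground"` or `"background"`.
#' @export
label_region_fg_bg <- function(region, gts, iogt_threshold = 0.5) {
  if (!is.numeric(iogt_threshold) || iogt_threshold <= 0 || iogt_threshold > 1)
    stop("iogt_threshold must lie in (0, 1]")
  if (is.null(gts) || !nrow(gts)) return("background")
  vals <- iogt(region[rep(1L, nrow(gts)), , drop = FALSE], gts)
  if (max(vals) < iogt_threshold) "background" else "foreground"
}

#' Tune-up boxes around an anchor
#'
#' Places one box of each preset `(width, height)` scale centered on the
#' anchor, giving the downstream patch classifier several view fields of
#' the same candidate object. Boxes are clipped to the image; clipped
#' boxes of area below 4 px^2 are dropped.
#'
#' @param center Numeric `(xc, yc)` anchor in pixel coordinates.
#' @param scales List of `(width, height)` pairs; all dims `>= 2`.
#' @param image_size Integer `(H, W)`.
#' @return A data frame of boxes with a `scale_index` column (1-based
#'   position in `scales`); clipping may drop rows but never renumbers.
#' @examples
#' tuneup_boxes(c(50, 50), list(c(20, 20)), c(100, 100)) # (40,40,60,60)
#' @export
tuneup_boxes <- function(center, scales, image_size) {
  H <- image_size[1]; W <- image_size[2]
  if (center[1] < 0 || center[1] > W || center[2] < 0 || center[2] > H)
    stop("anchor lies outside the image")
  if (!length(scales))
    return(data.frame(xmin = integer(0), ymin = integer(0),
                      xmax = integer(0), ymax = integer(0),
                      scale_index = integer(0)))
  if (any(vapply(scales, function(s) any(s < 2), logical(1))))
    stop("tune-up scale dimensions must be >= 2")
  b <- do.call(rbind, lapply(seq_along(scales), function(i) {
    s <- scales[[i]]
    xmin <- as.integer(round(center[1] - s[1] / 2))
    ymin <- as.integer(round(center[2] - s[2] / 2))
    data.frame(xmin = xmin, ymin = ymin,
               xmax = xmin + as.integer(s[1]), ymax = ymin + as.integer(s[2]),
               scale_index = i)
  }))
  clip_boxes(b, H, W, min_area = 4)
}

#' Generate region proposals from a saliency map
#'
#' The full proposal generator: saliency map, normalization, mask at
#' `alpha`, connected components, area filter at `beta`, then a
#' background/foreground decision per region -- against ground-truth
#' boxes via the `iogt` rule in training mode, or by running a patch
#' classifier on the region crop in inference mode. Every foreground
#' region emits its own bounding box (scale index 0) plus the k tune-up
#' boxes (indices 1..k); background regions emit nothing.
#'
#' @param image An `H x W x 3` array in `[0, 255]`.
#' @param gts Ground-truth data frame (training mode); `NULL` otherwise.
#' @param classifier A patch classifier (inference mode; see
#'   [oracle_classifier()]); any predicted label other than
#'   `"background"` opens the gate. Exactly one of `gts`/`classifier`
#'   must be given.
#' @param config Pipeline configuration (see [pest_config()]).
#' @return A data frame with columns `xmin`, `ymin`, `xmax`, `ymax`,
#'   `anchor_x`, `anchor_y`, `scale_index`.
#' @export
generate_proposals <- function(image, gts = NULL, classifier = NULL,
                               config = pest_config()) {
  validate_image(image)
  if (is.null(gts) == is.null(classifier))
    stop("supply exactly one of gts (training mode) or classifier (inference mode)")
  H <- dim(image)[1]; W <- dim(image)[2]

  S <- normalize_saliency(compute_saliency(image, sigma = config$sigma))
  M <- threshold_mask(S, config$alpha)
  regions <- area_filter(connected_components(M, config$connectivity),
                         config$beta)

  out <- empty_proposals()
  if (!nrow(regions)) return(out)
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, , drop = FALSE]
    fg <- if (!is.null(gts)) {
      label_region_fg_bg(reg, gts, config$iogt_threshold) == "foreground"
    } else {
      patch <- crop_with_padding(image, reg)
      predict_patch(classifier, patch)$label != "background"
    }
    if (!fg) next
    own <- data.frame(xmin = reg$xmin, ymin = reg$ymin,
                      xmax = reg$xmax, ymax = reg$ymax, scale_index = 0L)
    tune <- tuneup_boxes(c(reg$xc, reg$yc), config$scales, c(H, W))
    boxes <- rbind(own, tune)
    out <- rbind(out, data.frame(
      boxes[, c("xmin", "ymin", "xmax", "ymax")],
      anchor_x = reg$xc, anchor_y = reg$yc,
      scale_index = boxes$scale_index
    ))
  }
  rownames(out) <- NULL
  out
}

empty_proposals <- function() {
  data.frame(xmin = integer(0), ymin = integer(0), xmax = integer(0),
             ymax = integer(0), anchor_x = numeric(0), anchor_y = numeric(0),
             scale_index = integer(0))
}
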