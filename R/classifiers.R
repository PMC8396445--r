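#' Patch classifier contract
#'
#' A patch classifier is any object of class `"stickypest_classifier"`
#' with a `classes` field (ordered label vocabulary) and a `predict_fn`
#' taking an `H x W x 3` patch and returning
#' `list(label = <chr>, confidence = <num in [0,1]>)`.
#' [predict_patch()] dispatches on that contract, so users can plug in
#' their own models (e.g. an externally trained deep network) wherever
#' the pipeline expects `C1` (background/foreground gate) or `C2`
#' (category classifier).
#'
#' @param clf A classifier object.
#' @param patch An `H x W x 3` array in `[0, 255]`.
#' @return A list with elements `label` and `confidence`.
#' @export
predict_patch <- function(clf, patch) {
  UseMethod("predict_patch")
}

#' @export
predict_patch.stickypest_classifier <- function(clf, patch) {
  out <- clf$predict_fn(patch)
  stopifnot(is.character(out$label),
            out$confidence >= 0, out$confidence <= 1)
  if (!out$label %in% c(clf$classes, "background"))
    stop("classifier returned a label outside its vocabulary: ", out$label)
  out
}

new_classifier <- function(classes, predict_fn, ..., subclass = character()) {
  structure(list(classes = classes, predict_fn = predict_fn, ...),
            class = c(subclass, "stickypest_classifier"))
}

#' Crop a box from an image, padding with white
#'
#' Returns a patch of exactly the box's dimensions. Where the box
#' extends beyond the image border, the missing pixels are filled with
#' white `[255, 255, 255]`, which preserves the apparent object size on
#' the light trap background instead of shrinking the receptive field.
#'
#' @param image An `H x W x 3` array in `[0, 255]`.
#' @param b One-row box data frame; must overlap the image by at least
#'   one pixel.
#' @return A `(ymax-ymin) x (xmax-xmin) x 3` array.
#' @export
crop_with_padding <- function(image, b) {
  validate_image(image)
  validate_boxes(b)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (b$xmax <= 0 || b$xmin >= W || b$ymax <= 0 || b$ymin >= H)
    stop("box lies fully outside the image")
  ph <- b$ymax - b$ymin; pw <- b$xmax - b$xmin
  patch <- array(255, c(ph, pw, 3L))
  ys <- max(b$ymin, 0L):(min(b$ymax, H) - 1L)  # 0-based source rows
  xs <- max(b$xmin, 0L):(min(b$xmax, W) - 1L)
  patch[ys - b$ymin + 1L, xs - b$xmin + 1L, ] <-
    image[ys + 1L, xs + 1L, , drop = FALSE]
  patch
}

#' Resize a patch
#'
#' Bilinear resize to a square side, used to bring variably sized region
#' proposals to a fixed classifier input size.
#'
#' @param patch An `H x W x 3` array in `[0, 255]`.
#' @param side Target side length in pixels.
#' @return A `side x side x 3` array in `[0, 255]`.
#' @export
resize_patch <- function(patch, side) {
  if (dim(patch)[1] == side && dim(patch)[2] == side) return(patch)
  out <- from_ebimage(EBImage::resize(as_ebimage(patch), w = side, h = side))
  pmin(pmax(out, 0), 255)
}

#' Training labels for the category classifier
#'
#' Labels each region proposal with the class of the ground-truth box it
#' overlaps best, provided that best `iou` reaches `iou_threshold`;
#' proposals below the threshold for every ground truth are labelled
#' `"background"`. Patches are cropped with white padding and resized to
#' the classifier input side.
#'
#' @param proposals Proposal data frame (see [generate_proposals()]).
#' @param gts Ground-truth data frame (`xmin..ymax`, `label`).
#' @param image Source image array.
#' @param iou_threshold Threshold in `(0, 1]` (default 0.5).
#' @param patch_side Classifier input side (default 64).
#' @return A list of training examples, each
#'   `list(patch = <array>, label = <chr>)`.
#' @export
make_c2_labels <- function(proposals, gts, image, iou_threshold = 0.5,
                           patch_side = 64) {
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]")
  lapply(seq_len(nrow(proposals)), function(i) {
    p <- proposals[i, , drop = FALSE]
    label <- "background"
    if (!is.null(gts) && nrow(gts)) {
      ious <- iou(p[rep(1L, nrow(gts)), , drop = FALSE], gts)
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) label <- gts$label[j]
    }
    patch <- resize_patch(crop_with_padding(image, p), patch_side)
    list(patch = patch, label = label)
  })
}

#' Deterministic mean-colour oracle classifier
#'
#' A test double standing in for a trained patch classifier: it predicts
#' from the mean colour of the central half of the patch. Each rule maps
#' an RGB range (`lo`/`hi` per channel) to a label; a patch whose
#' central mean falls inside a rule's range gets that label with
#' confidence 1.0, and any other patch is `"background"` with
#' confidence 1.0. Rule ranges must not overlap.
#'
#' @param rules Named list; each element is `list(lo = c(r,g,b),
#'   hi = c(r,g,b))` and the element name is the predicted label.
#' @return A classifier usable with [predict_patch()].
#' @examples
#' clf <- oracle_classifier(list(
#'   "diamondback moth" = list(lo = c(30, 20, 25), hi = c(160, 150, 60)),
#'   "others" = list(lo = c(0, 0, 0), hi = c(29, 150, 60))))
#' @export
oracle_classifier <- function(rules) {
  stopifnot(is.list(rules), length(names(rules)) == length(rules))
  for (rule in rules)
    stopifnot(length(rule$lo) == 3L, length(rule$hi) == 3L,
              all(rule$lo <= rule$hi))
  if (length(rules) > 1L) {
    for (i in seq_len(length(rules) - 1L)) for (j in (i + 1L):length(rules)) {
      a <- rules[[i]]; b <- rules[[j]]
      if (all(a$lo <= b$hi) && all(b$lo <= a$hi))
        stop("overlapping colour rules: ", names(rules)[i], " and ",
             names(rules)[j])
    }
  }
  predict_fn <- function(patch) {
    m <- central_mean_colour(patch)
    for (k in seq_along(rules)) {
      if (all(m >= rules[[k]]$lo) && all(m <= rules[[k]]$hi))
        return(list(label = names(rules)[k], confidence = 1.0))
    }
    list(label = "background", confidence = 1.0)
  }
  new_classifier(names(rules), predict_fn, rules = rules,
                 subclass = "oracle_classifier")
}

# Mean RGB over the central half (half the side in each dimension,
# centered) of a patch.
central_mean_colour <- function(patch) {
  h <- dim(patch)[1]; w <- dim(patch)[2]
  ys <- seq.int(floor(h / 4) + 1L, length.out = max(1L, floor(h / 2)))
  xs <- seq.int(floor(w / 4) + 1L, length.out = max(1L, floor(w / 2)))
  apply(patch[ys, xs, , drop = FALSE], 3L, mean)
}

#' Constant classifier
#'
#' Always predicts the same label with confidence 1; useful for forcing
#' the background/foreground gate open or closed in tests.
#'
#' @param label The label to predict.
#' @return A classifier usable with [predict_patch()].
#' @export
constant_classifier <- function(label) {
  new_classifier(label, function(patch) list(label = label, confidence = 1.0))
}
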