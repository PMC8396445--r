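#' Detect insects in a trap image
#'
#' Runs the full single-image pipeline: saliency-based region proposals
#' gated by the background/foreground classifier `c1`, category
#' classification of every proposal patch by `c2`, and improved
#' non-maximum suppression of the resulting detections.
#'
#' @param image An `H x W x 3` array in `[0, 255]`.
#' @param c1 Background/foreground gate classifier; any label other
#'   than `"background"` opens the gate (see [predict_patch()]).
#' @param c2 Category classifier; proposals it labels `"background"`
#'   are dropped.
#' @param config Pipeline configuration (see [pest_config()]).
#' @return A detection data frame (see [detection()]).
#' @export
detect_insects <- function(image, c1, c2, config = pest_config()) {
  proposals <- generate_proposals(image, classifier = c1, config = config)
  dets <- empty_detections()
  for (i in seq_len(nrow(proposals))) {
    p <- proposals[i, , drop = FALSE]
    patch <- crop_with_padding(image, p)
    pred <- predict_patch(c2, patch)
    if (pred$label == "background") next
    dets <- rbind(dets, detection(p$xmin, p$ymin, p$xmax, p$ymax,
                                  pred$label, pred$confidence))
  }
  inms(dets,
       merge_iou_threshold = config$merge_iou_threshold,
       nms_iou_threshold = config$nms_iou_threshold,
       gamma = config$gamma)
}

#' Oracle classifiers for the synthetic scenes
#'
#' Deterministic [oracle_classifier()] instances tuned to the synthetic
#' stand-in colours of [scene_params()]: the gate classifier declares
#' any patch whose central mean is clearly darker than the yellow
#' background to be `"foreground"`, and the category classifier
#' separates the two insect classes by their red-channel level. These
#' exist so the whole pipeline can be exercised and evaluated without a
#' trained network; they know nothing about real trap images.
#'
#' @return A classifier usable with [predict_patch()].
#' @export
synthetic_gate_classifier <- function() {
  oracle_classifier(list(
    foreground = list(lo = c(0, 0, 0), hi = c(200, 255, 255))))
}

#' @rdname synthetic_gate_classifier
#' @export
synthetic_category_classifier <- function() {
  oracle_classifier(list(
    "diamondback moth" = list(lo = c(45, 35, 25), hi = c(140, 125, 58)),
    "others" = list(lo = c(0, 0, 0), hi = c(44, 60, 45))))
}

#' Detect over a directory of images
#'
#' Applies [detect_insects()] to every PNG/JPEG in a directory and
#' stacks the results with an `image` column, in sorted file order.
#'
#' @inheritParams detect_insects
#' @param dir Directory of images.
#' @return A detection data frame with a leading `image` column.
#' @export
detect_directory <- function(dir, c1, c2, config = pest_config()) {
  files <- sort(list.files(dir, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE))
  out <- cbind(image = character(0), empty_detections())
  for (f in files) {
    dets <- detect_insects(read_image(file.path(dir, f)), c1, c2, config)
    if (nrow(dets)) out <- rbind(out, cbind(image = f, dets))
  }
  rownames(out) <- NULL
  out
}

#' Evaluate a detections file against VOC annotations
#'
#' Joins a multi-image detection data frame (with `image` column)
#' against the VOC annotations of a directory, by image file name, and
#' computes the full metrics report. Images that have annotations but
#' no detections contribute false negatives.
#'
#' @param dets Detection data frame with an `image` column.
#' @param voc_dir Directory of VOC XML annotation files.
#' @return A `"pest_metrics"` object (see [evaluate_detections()]).
#' @export
evaluate_against_voc <- function(dets, voc_dir) {
  files <- sort(list.files(voc_dir, pattern = "\\.xml$", full.names = TRUE))
  if (!length(files)) stop("no VOC annotations found in ", voc_dir)
  dets_list <- list(); gts_list <- list()
  for (f in files) {
    ann <- read_voc(f)
    img <- ann$filename
    d <- dets[dets$image == img, , drop = FALSE]
    d$image <- NULL
    if (!nrow(d)) d <- empty_detections()
    dets_list[[img]] <- d
    gts_list[[img]] <- ann$gts
  }
  evaluate_detections(dets_list, gts_list)
}
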