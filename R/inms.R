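#' Detections
#'
#' A detection set is a data frame with columns `xmin`, `ymin`, `xmax`,
#' `ymax` (0-based half-open pixels), `label` (class name, never
#' `"background"`) and `confidence` in `[0, 1]`.
#'
#' @param xmin,ymin,xmax,ymax Box edges.
#' @param label Class label.
#' @param confidence Score in `[0, 1]`.
#' @return A detection data frame.
#' @export
detection <- function(xmin, ymin, xmax, ymax, label, confidence) {
  d <- data.frame(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
                  label = label, confidence = confidence,
                  stringsAsFactors = FALSE)
  validate_detections(d)
  d
}

validate_detections <- function(d) {
  validate_boxes(d)
  stopifnot(all(c("label", "confidence") %in% names(d)))
  if (nrow(d) && (any(d$confidence < 0) || any(d$confidence > 1)))
    stop("detection confidence must lie in [0, 1]")
  invisible(d)
}

empty_detections <- function() {
  detection(integer(0), integer(0), integer(0), integer(0),
            character(0), numeric(0))
}

#' Conventional non-maximum suppression
#'
#' Greedy class-agnostic suppression: repeatedly keep the
#' highest-confidence remaining detection and discard every other
#' detection whose `iou` with it exceeds `iou_threshold`.
#'
#' @param dets Detection data frame.
#' @param iou_threshold Overlap threshold in `(0, 1)`.
#' @return The surviving detections, sorted by descending confidence.
#' @export
nms <- function(dets, iou_threshold = 0.3) {
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("iou_threshold must lie in (0, 1)")
  validate_detections(dets)
  if (nrow(dets) <= 1L) return(dets)
  # Confidence ties: prefer the tighter (smaller-area) box, so a loose
  # duplicate never suppresses the tight detection it duplicates.
  ord <- order(-dets$confidence, box_area(dets), dets$xmin, dets$ymin)
  dets <- dets[ord, , drop = FALSE]
  keep <- logical(nrow(dets))
  alive <- rep(TRUE, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    rest <- which(alive & seq_len(nrow(dets)) > i)
    if (length(rest)) {
      ious <- iou(dets[i, , drop = FALSE], dets[rest, , drop = FALSE])
      alive[rest[ious > iou_threshold]] <- FALSE
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge two same-class detections
#'
#' The merged box is the confidence-weighted average of the two boxes'
#' coordinates (rounded to integer pixels) and the merged confidence is
#' the noisy-OR `1 - (1 - c0)(1 - c1)`, so agreement between two
#' detections of the same object strictly increases confidence.
#'
#' @param b0,b1 One-row detection data frames with equal labels.
#' @return A one-row merged detection.
#' @examples
#' merge_detections(detection(0, 0, 10, 10, "m", 0.5),
#'                  detection(10, 0, 20, 10, "m", 0.5))
#' @export
merge_detections <- function(b0, b1) {
  validate_detections(b0); validate_detections(b1)
  if (b0$label != b1$label)
    stop("cannot merge detections with different labels")
  w0 <- b0$confidence; w1 <- b1$confidence
  if (w0 + w1 == 0) { w0 <- 1; w1 <- 1 }
  avg <- function(a, b) as.integer(round((w0 * a + w1 * b) / (w0 + w1)))
  detection(avg(b0$xmin, b1$xmin), avg(b0$ymin, b1$ymin),
            avg(b0$xmax, b1$xmax), avg(b0$ymax, b1$ymax),
            b0$label,
            1 - (1 - b0$confidence) * (1 - b1$confidence))
}

# Deterministic working order of the merge phase: ascending box area,
# ties broken by (xmin, ymin, confidence, label).
inms_order <- function(d) {
  order(box_area(d), d$xmin, d$ymin, d$confidence, d$label)
}

# Merge loop of the improved NMS: repeatedly take the least-area
# detection, merge it into the first same-class detection it overlaps
# beyond the threshold (re-sorting afterwards), or move it to the
# holding set when nothing matches.
inms_merge_phase <- function(dets, merge_iou_threshold) {
  work <- dets[inms_order(dets), , drop = FALSE]
  hold <- empty_detections()
  while (nrow(work)) {
    b0 <- work[1L, , drop = FALSE]
    rest <- work[-1L, , drop = FALSE]
    merged_at <- NA_integer_
    if (nrow(rest)) {
      for (i in seq_len(nrow(rest))) {
        if (rest$label[i] == b0$label &&
            iou(b0, rest[i, , drop = FALSE]) > merge_iou_threshold) {
          merged_at <- i
          break
        }
      }
    }
    if (is.na(merged_at)) {
      hold <- rbind(hold, b0)
      work <- rest
    } else {
      rest[merged_at, ] <- merge_detections(b0, rest[merged_at, , drop = FALSE])
      work <- rest[inms_order(rest), , drop = FALSE]
    }
  }
  rownames(hold) <- NULL
  hold
}

#' Improved non-maximum suppression
#'
#' Three phases. (1) Merge: detections are scanned in ascending order of
#' box area; the smallest detection is merged (see [merge_detections()])
#' into the first same-class detection it overlaps with
#' `iou > merge_iou_threshold`, and the working set is re-sorted; a
#' detection that overlaps nothing moves to the holding set. The merge
#' boosts the confidence of repeatedly detected objects. (2) The holding
#' set goes through conventional [nms()] at `nms_iou_threshold`.
#' (3) Only detections with `confidence >= gamma` are kept. The merge
#' step prevents a single confident false positive from suppressing a
#' cluster of weaker true positives of the correct class.
#'
#' @param dets Detection data frame.
#' @param merge_iou_threshold Overlap required to merge, in `(0, 1)`.
#' @param nms_iou_threshold Suppression overlap threshold, in `(0, 1)`.
#' @param gamma Minimum surviving confidence in `[0, 1]`.
#' @return The final detections, sorted by descending confidence.
#' @export
inms <- function(dets, merge_iou_threshold = 0.5, nms_iou_threshold = 0.3,
                 gamma = 0.5) {
  if (merge_iou_threshold <= 0 || merge_iou_threshold >= 1)
    stop("merge_iou_threshold must lie in (0, 1)")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  validate_detections(dets)
  if (!nrow(dets)) return(dets)
  hold <- inms_merge_phase(dets, merge_iou_threshold)
  out <- nms(hold, nms_iou_threshold)
  out <- out[out$confidence >= gamma, , drop = FALSE]
  rownames(out) <- NULL
  out
}
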