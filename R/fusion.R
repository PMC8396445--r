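#' Dual-path fusion of detection sets
#'
#' Combines an external detector's boxes (high recall, more false
#' positives; e.g. a sliding-window or anchor-based detector) with the
#' saliency pipeline's boxes (high precision, but prone to merging
#' insects that sit close together). An external detection is retained
#' exactly when it overlaps at least one pipeline detection
#' (`iou > 0`); otherwise it is treated as a false detection and
#' dropped. Confidences are left unchanged. With `union_mode = TRUE`,
#' pipeline detections that no external box overlaps are appended as
#' well.
#'
#' @param external_dets Detection data frame from the external detector.
#' @param proposed_dets Detection data frame from the saliency pipeline.
#' @param union_mode Also emit unmatched pipeline detections
#'   (default `FALSE`).
#' @return A detection data frame.
#' @export
fuse_detections <- function(external_dets, proposed_dets,
                            union_mode = FALSE) {
  validate_detections(external_dets)
  validate_detections(proposed_dets)
  keep <- logical(nrow(external_dets))
  if (nrow(external_dets) && nrow(proposed_dets)) {
    for (i in seq_len(nrow(external_dets))) {
      keep[i] <- any(iou(external_dets[i, , drop = FALSE],
                         proposed_dets) > 0)
    }
  }
  out <- external_dets[keep, , drop = FALSE]
  if (union_mode && nrow(proposed_dets)) {
    unmatched <- rep(TRUE, nrow(proposed_dets))
    if (nrow(external_dets)) {
      for (j in seq_len(nrow(proposed_dets))) {
        unmatched[j] <- !any(iou(proposed_dets[j, , drop = FALSE],
                                 external_dets) > 0)
      }
    }
    out <- rbind(out, proposed_dets[unmatched, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
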