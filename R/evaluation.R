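#' Count detections
#'
#' After improved non-maximum suppression each remaining detection
#' covers one insect, so the insect count is simply the number of
#' detections.
#'
#' @param dets Detection data frame (already INMS-processed).
#' @return Integer count.
#' @export
count_detections <- function(dets) {
  validate_detections(dets)
  nrow(dets)
}

#' Match detections against ground truth
#'
#' A detection is "correct" for a ground-truth box when the labels match
#' and `iogt(det, gt) >= 0.5`. Each detection is assigned to the ground
#' truth it overlaps best among those it is correct for; per ground
#' truth, only the assigned detection with the highest `iogt` is a true
#' positive and any others are false positives. Detections correct for
#' no ground truth are false positives; ground truths without a true
#' positive are false negatives. Each detection is counted exactly once.
#'
#' @param dets Detection data frame.
#' @param gts Ground-truth data frame (`xmin..ymax`, `label`).
#' @return A list with integer counts `TP`, `FP`, `FN`.
#' @export
match_detections <- function(dets, gts) {
  nd <- nrow(dets); ng <- if (is.null(gts)) 0L else nrow(gts)
  if (!nd) return(list(TP = 0L, FP = 0L, FN = ng))
  if (!ng) return(list(TP = 0L, FP = nd, FN = 0L))
  # assignment[i]: ground truth claimed by detection i, NA when none
  assignment <- rep(NA_integer_, nd)
  best_iogt <- rep(NA_real_, nd)
  for (i in seq_len(nd)) {
    d <- dets[i, , drop = FALSE]
    vals <- iogt(d[rep(1L, ng), , drop = FALSE], gts)
    vals[gts$label != d$label] <- -1
    j <- which.max(vals)
    if (vals[j] >= 0.5) {
      assignment[i] <- j
      best_iogt[i] <- vals[j]
    }
  }
  TP <- 0L
  for (j in seq_len(ng)) {
    claimants <- which(assignment == j)
    if (length(claimants)) TP <- TP + 1L   # best claimant is the TP
  }
  list(TP = TP, FP = nd - TP, FN = ng - TP)
}

#' Precision and recall from match counts
#'
#' `R = TP / (TP + FN)`, `P = TP / (TP + FP)`; both defined as 0 when
#' their denominator is 0. The detection rate DR equals recall and the
#' false detection rate FDR equals `1 - P`.
#'
#' @param TP,FP,FN Non-negative integer counts.
#' @return A list with elements `P` and `R`.
#' @export
precision_recall <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  list(P = if (TP + FP > 0) TP / (TP + FP) else 0,
       R = if (TP + FN > 0) TP / (TP + FN) else 0)
}

#' F1 score from detection rate and false detection rate
#'
#' `F1 = 2 * DR * (1 - FDR) / (DR + (1 - FDR))`, the harmonic mean of
#' recall (`DR`) and precision (`1 - FDR`); 0 when both vanish.
#'
#' @param DR Detection rate (recall), in `[0, 1]`.
#' @param FDR False detection rate (`1 -` precision), in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(0.857, 0.065) # ~0.894
#' @export
f1_score <- function(DR, FDR) {
  stopifnot(DR >= 0, DR <= 1, FDR >= 0, FDR <= 1)
  P <- 1 - FDR
  if (DR + P == 0) return(0)
  2 * DR * P / (DR + P)
}

#' Counting error of predicted versus true insect numbers
#'
#' Mean absolute error and mean squared error over per-image count
#' pairs: `MAE = mean(|z - zhat|)`, `MSE = mean((z - zhat)^2)`.
#'
#' @param predicted Numeric vector of predicted counts (`zhat`).
#' @param truth Numeric vector of true counts (`z`), same length.
#' @return A list with elements `MAE` and `MSE`.
#' @export
mae_mse <- function(predicted, truth) {
  if (!length(predicted)) stop("need at least one count pair")
  if (length(predicted) != length(truth))
    stop("predicted and truth must have the same length")
  list(MAE = mean(abs(truth - predicted)),
       MSE = mean((truth - predicted)^2))
}

#' Evaluate a detection set over a test collection
#'
#' Aggregates [match_detections()] counts over images, derives DR, FDR,
#' precision, recall and F1, and computes the counting errors MAE and
#' MSE from per-image counts.
#'
#' @param dets_list List of detection data frames, one per image.
#' @param gts_list List of ground-truth data frames, same length/order.
#' @return A list of class `"pest_metrics"`: counts `TP`, `FP`, `FN`,
#'   rates `DR`, `FDR`, `P`, `R`, `F1`, errors `MAE`, `MSE`, and
#'   `per_image_counts` (data frame with `predicted`, `truth`).
#' @export
evaluate_detections <- function(dets_list, gts_list) {
  stopifnot(length(dets_list) == length(gts_list))
  TP <- FP <- FN <- 0L
  predicted <- truth <- integer(length(dets_list))
  for (i in seq_along(dets_list)) {
    m <- match_detections(dets_list[[i]], gts_list[[i]])
    TP <- TP + m$TP; FP <- FP + m$FP; FN <- FN + m$FN
    predicted[i] <- nrow(dets_list[[i]])
    truth[i] <- if (is.null(gts_list[[i]])) 0L else nrow(gts_list[[i]])
  }
  pr <- precision_recall(TP, FP, FN)
  err <- mae_mse(predicted, truth)
  structure(list(
    TP = TP, FP = FP, FN = FN,
    DR = pr$R, FDR = 1 - pr$P, P = pr$P, R = pr$R,
    F1 = f1_score(pr$R, 1 - pr$P),
    MAE = err$MAE, MSE = err$MSE,
    per_image_counts = data.frame(predicted = predicted, truth = truth)
  ), class = "pest_metrics")
}

#' @export
print.pest_metrics <- function(x, ...) {
  cat(sprintf("pest detection metrics over %d images\n",
              nrow(x$per_image_counts)))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$TP, x$FP, x$FN))
  cat(sprintf("  DR %.3f  FDR %.3f  F1 %.3f\n", x$DR, x$FDR, x$F1))
  cat(sprintf("  MAE %.3f  MSE %.3f\n", x$MAE, x$MSE))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param metrics A `"pest_metrics"` object from [evaluate_detections()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  out <- unclass(metrics)
  out$per_image_counts <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
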