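#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default.
#' Unknown keys are rejected, and each threshold is validated against
#' its documented range.
#'
#' \describe{
#'   \item{sigma}{Saliency blur standard deviation, px (default 3).}
#'   \item{alpha}{Saliency mask threshold on the normalized `[0, 1]`
#'     scale (default 0.10).}
#'   \item{beta}{Minimum activation-region box area, px^2 (default 30).}
#'   \item{connectivity}{4 or 8 for component linking (default 8).}
#'   \item{iogt_threshold}{Foreground gate threshold in training mode
#'     (default 0.5).}
#'   \item{scales}{List of tune-up `(width, height)` pairs; default
#'     `(24,24), (32,32), (44,44)` for insects in the 12-36 px range.}
#'   \item{iou_label_threshold}{Category-label `iou` threshold for
#'     training examples (default 0.5).}
#'   \item{merge_iou_threshold}{Minimum overlap for merging two
#'     same-class detections (default 0.5).}
#'   \item{nms_iou_threshold}{Suppression overlap threshold of the final
#'     conventional NMS (default 0.3; concentric multi-scale detections
#'     of one anchor often overlap a larger merged box by only ~0.4, so
#'     the common stricter setting is used).}
#'   \item{gamma}{Minimum confidence for a detection to survive
#'     (default 0.5).}
#'   \item{classes}{Annotation vocabulary (default
#'     `"diamondback moth"`, `"others"`).}
#'   \item{patch_side}{Classifier input side, px (default 64).}
#'   \item{union_mode}{Dual-path fusion: also emit pipeline detections
#'     unmatched by the external detector (default `FALSE`).}
#'   \item{seed}{Base seed for stochastic components (default 1).}
#' }
#'
#' @param ... Named overrides of the defaults above.
#' @return A named list of class `"pest_config"`.
#' @examples
#' cfg <- pest_config(alpha = 0.15, gamma = 0.6)
#' @export
pest_config <- function(...) {
  cfg <- list(
    sigma = 3, alpha = 0.10, beta = 30, connectivity = 8,
    iogt_threshold = 0.5,
    scales = list(c(24, 24), c(32, 32), c(44, 44)),
    iou_label_threshold = 0.5,
    merge_iou_threshold = 0.5, nms_iou_threshold = 0.3, gamma = 0.5,
    classes = c("diamondback moth", "others"),
    patch_side = 64, union_mode = FALSE, seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pest_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$sigma > 0, cfg$beta >= 0,
            cfg$alpha >= 0, cfg$alpha <= 1,
            cfg$connectivity %in% c(4, 8),
            cfg$iogt_threshold > 0, cfg$iogt_threshold <= 1,
            cfg$iou_label_threshold > 0, cfg$iou_label_threshold <= 1,
            cfg$merge_iou_threshold > 0, cfg$merge_iou_threshold < 1,
            cfg$nms_iou_threshold > 0, cfg$nms_iou_threshold < 1,
            cfg$gamma >= 0, cfg$gamma <= 1,
            cfg$patch_side >= 8,
            is.logical(cfg$union_mode))
  invisible(cfg)
}

#' Read and write pipeline configuration files
#'
#' Configurations serialize to JSON and round-trip exactly; unknown
#' keys in a file are rejected on read.
#'
#' @param cfg A configuration from [pest_config()].
#' @param path File path (JSON).
#' @return `read_config()` returns a validated `"pest_config"`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$scales)) {
    if (is.matrix(raw$scales))
      raw$scales <- lapply(seq_len(nrow(raw$scales)),
                           function(i) raw$scales[i, ])
    else raw$scales <- lapply(raw$scales, as.numeric)
  }
  if (!is.null(raw$seed)) raw$seed <- as.integer(raw$seed)
  do.call(pest_config, raw)
}
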