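#' Read and write detection files
#'
#' Detections serialize as CSV with columns
#' `xmin,ymin,xmax,ymax,label,confidence` (plus an optional leading
#' `image` column when several images share one file) or as JSON.
#' Confidences are written with full precision, so a write/read cycle
#' reproduces the numbers bit for bit.
#'
#' @param dets Detection data frame; may carry an `image` column.
#' @param path Output path.
#' @return Readers return a detection data frame; writers return `path`
#'   invisibly.
#' @export
write_detections_csv <- function(dets, path) {
  validate_detections(dets)
  out <- dets
  out$confidence <- sprintf("%.17g", out$confidence)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$confidence <- as.numeric(d$confidence)
  for (col in c("xmin", "ymin", "xmax", "ymax"))
    d[[col]] <- as.integer(d[[col]])
  if (nrow(d)) validate_detections(d)
  d
}

#' @rdname write_detections_csv
#' @export
write_detections_json <- function(dets, path) {
  validate_detections(dets)
  jsonlite::write_json(dets, path, digits = I(17), dataframe = "rows")
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_json <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  if (!nrow(d))
    return(empty_detections())
  for (col in c("xmin", "ymin", "xmax", "ymax"))
    d[[col]] <- as.integer(d[[col]])
  d$confidence <- as.numeric(d$confidence)
  validate_detections(d)
  d
}

#' Export proposals as CSV
#'
#' Columns: `xmin,ymin,xmax,ymax,anchor_x,anchor_y,scale_index`.
#'
#' @param proposals Proposal data frame from [generate_proposals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proposals_csv <- function(proposals, path) {
  utils::write.csv(proposals, path, row.names = FALSE)
  invisible(path)
}
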