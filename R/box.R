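#' Axis-aligned box geometry
#'
#' Boxes are axis-aligned rectangles in pixel coordinates, 0-based and
#' half-open: a box `(xmin, ymin, xmax, ymax)` covers columns
#' `[xmin, xmax)` and rows `[ymin, ymax)`, so its area is
#' `(xmax - xmin) * (ymax - ymin)`. `x` indexes columns and `y` rows.
#'
#' @param xmin,ymin,xmax,ymax Box edges in pixels; `xmin < xmax` and
#'   `ymin < ymax` are required.
#' @return `box()` returns a one-row data frame with columns
#'   `xmin`, `ymin`, `xmax`, `ymax`.
#' @examples
#' b <- box(0, 0, 10, 5)
#' box_area(b)
#' @export
box <- function(xmin, ymin, xmax, ymax) {
  b <- data.frame(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  validate_boxes(b)
  b
}

validate_boxes <- function(b) {
  stopifnot(is.data.frame(b),
            all(c("xmin", "ymin", "xmax", "ymax") %in% names(b)))
  if (nrow(b) && (any(b$xmin >= b$xmax) || any(b$ymin >= b$ymax)))
    stop("degenerate box: xmin < xmax and ymin < ymax are required")
  invisible(b)
}

#' @rdname box
#' @param b A data frame of boxes.
#' @export
box_area <- function(b) {
  (b$xmax - b$xmin) * (b$ymax - b$ymin)
}

# Intersection area of one box against each row of a box data frame.
box_intersection <- function(b0, b) {
  iw <- pmin(b0$xmax, b$xmax) - pmax(b0$xmin, b$xmin)
  ih <- pmin(b0$ymax, b$ymax) - pmax(b0$ymin, b$ymin)
  pmax(iw, 0) * pmax(ih, 0)
}

#' Intersection over union of two boxes
#'
#' `iou(b0, b1)` is the ratio of the intersection area to the union area
#' of two boxes; it is 0 for disjoint boxes and 1 for identical ones.
#'
#' @param b0,b1 One-row box data frames (see [box()]).
#' @return A number in `[0, 1]`.
#' @examples
#' iou(box(0, 0, 10, 10), box(5, 0, 15, 10)) # 1/3
#' @export
iou <- function(b0, b1) {
  validate_boxes(b0); validate_boxes(b1)
  inter <- box_intersection(b0, b1)
  inter / (box_area(b0) + box_area(b1) - inter)
}

#' Intersection over ground-truth area
#'
#' `iogt(a, bgt)` divides the intersection area of a candidate box `a`
#' with a ground-truth box `bgt` by the area of `bgt`. It is the overlap
#' measure used both to gate activation regions against annotations and
#' to decide whether a detection counts as correct.
#'
#' @param a Candidate box (one-row data frame).
#' @param bgt Ground-truth box (one-row data frame).
#' @return A number in `[0, 1]`: 1 when `a` contains `bgt` entirely,
#'   0 when they are disjoint.
#' @examples
#' iogt(box(0, 0, 10, 5), box(0, 0, 10, 10)) # 0.5
#' @export
iogt <- function(a, bgt) {
  validate_boxes(a); validate_boxes(bgt)
  box_intersection(a, bgt) / box_area(bgt)
}

# Clip a box data frame to image bounds [0, W) x [0, H); rows whose
# clipped area falls below min_area are dropped.
clip_boxes <- function(b, height, width, min_area = 1) {
  if (!nrow(b)) return(b)
  b$xmin <- pmax(b$xmin, 0L)
  b$ymin <- pmax(b$ymin, 0L)
  b$xmax <- pmin(b$xmax, width)
  b$ymax <- pmin(b$ymax, height)
  keep <- b$xmax > b$xmin & b$ymax > b$ymin &
    (b$xmax - b$xmin) * (b$ymax - b$ymin) >= min_area
  b[keep, , drop = FALSE]
}
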