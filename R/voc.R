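#' Read a PASCAL VOC annotation file
#'
#' Parses the LabelImg dialect of PASCAL VOC XML: object `name` plus
#' `bndbox` coordinates. VOC stores 1-based inclusive pixel indices;
#' they are converted to the package's 0-based half-open convention as
#' `(xmin - 1, ymin - 1, xmax, ymax)`, so a VOC box `(1, 1, 10, 10)`
#' becomes the internal box `(0, 0, 10, 10)` with area 100.
#'
#' @param path Path to the XML file.
#' @return A list with `filename`, `width`, `height`, and `gts` (data
#'   frame `xmin`, `ymin`, `xmax`, `ymax`, `label` in document order).
#' @export
read_voc <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed VOC XML in ", path,
                                           ": ", conditionMessage(e)))
  size <- xml2::xml_find_first(doc, "./size")
  objects <- xml2::xml_find_all(doc, "./object")
  gts <- data.frame(xmin = integer(0), ymin = integer(0),
                    xmax = integer(0), ymax = integer(0),
                    label = character(0), stringsAsFactors = FALSE)
  for (obj in objects) {
    bnd <- xml2::xml_find_first(obj, "./bndbox")
    if (is.na(bnd)) stop("object without bndbox in ", path)
    num <- function(tag) {
      v <- xml2::xml_double(xml2::xml_find_first(bnd, paste0("./", tag)))
      if (is.na(v)) stop("missing <", tag, "> in ", path)
      v
    }
    gts <- rbind(gts, data.frame(
      xmin = as.integer(num("xmin")) - 1L,
      ymin = as.integer(num("ymin")) - 1L,
      xmax = as.integer(num("xmax")),
      ymax = as.integer(num("ymax")),
      label = xml2::xml_text(xml2::xml_find_first(obj, "./name")),
      stringsAsFactors = FALSE))
  }
  list(filename = xml2::xml_text(xml2::xml_find_first(doc, "./filename")),
       width = if (!is.na(size))
         as.integer(xml2::xml_double(xml2::xml_find_first(size, "./width")))
       else NA_integer_,
       height = if (!is.na(size))
         as.integer(xml2::xml_double(xml2::xml_find_first(size, "./height")))
       else NA_integer_,
       gts = gts)
}

#' Write a PASCAL VOC annotation file
#'
#' Inverse of [read_voc()]: internal 0-based half-open boxes are written
#' back as 1-based inclusive VOC coordinates
#' `(xmin + 1, ymin + 1, xmax, ymax)`. Field order is fixed, so
#' regenerating a file from the same annotations is byte-identical.
#'
#' @param gts Ground-truth data frame (`xmin..ymax`, `label`).
#' @param path Output XML path.
#' @param filename Image file name recorded in the annotation.
#' @param width,height Image size in pixels.
#' @return `path`, invisibly.
#' @export
write_voc <- function(gts, path, filename, width, height) {
  validate_boxes(gts)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", filename)
  xml2::xml_add_child(doc, "path", filename)
  src <- xml2::xml_add_child(doc, "source")
  xml2::xml_add_child(src, "database", "Unknown")
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(width))
  xml2::xml_add_child(size, "height", as.character(height))
  xml2::xml_add_child(size, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  for (i in seq_len(nrow(gts))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", gts$label[i])
    xml2::xml_add_child(obj, "pose", "Unspecified")
    xml2::xml_add_child(obj, "truncated", "0")
    xml2::xml_add_child(obj, "difficult", "0")
    bnd <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bnd, "xmin", as.character(gts$xmin[i] + 1L))
    xml2::xml_add_child(bnd, "ymin", as.character(gts$ymin[i] + 1L))
    xml2::xml_add_child(bnd, "xmax", as.character(gts$xmax[i]))
    xml2::xml_add_child(bnd, "ymax", as.character(gts$ymax[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read all VOC annotations in a directory
#'
#' @param dir Directory containing `.xml` files.
#' @return A named list of ground-truth data frames, keyed and ordered
#'   by file name.
#' @export
read_voc_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  out <- lapply(files, function(f) read_voc(f)$gts)
  names(out) <- basename(files)
  out
}
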