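# Annotation containers: NucleusAnnotation and LabelSet.

#' Create a nucleus annotation
#'
#' @param polygon Vertex matrix (x, y), >= 3 vertices, simple polygon.
#' @param cls Class label; matched case-insensitively against
#'   `"yin"`, `"yin-yang"`, `"yang"` and normalized to lower case.
#' @param validate Check polygon simplicity (O(n^2); skip for bulk
#'   generator-internal construction where shapes are simple by design).
#' @return Object of class `nucleus_annotation`.
#' @export
nucleus_annotation <- function(polygon, cls, validate = TRUE) {
  polygon <- as_polygon(polygon)
  cls <- normalize_class(cls)
  if (validate && !polygon_is_simple(polygon))
    stop("nucleus_annotation: polygon is self-intersecting")
  structure(list(polygon = polygon, cls = cls), class = "nucleus_annotation")
}

normalize_class <- function(cls) {
  if (length(cls) != 1L) stop("cls must be a single string")
  lc <- tolower(gsub("_", "-", as.character(cls)))
  if (!lc %in% .CLASSES)
    stop(sprintf("unknown nucleus class '%s' (expected yin, yin-yang or yang)", cls))
  lc
}

#' Create a label set (all nucleus annotations of one image)
#'
#' @param image_id Image identifier (string).
#' @param height,width Image dimensions in pixels.
#' @param annotations List of [nucleus_annotation()] objects.
#' @return Object of class `label_set`.
#' @export
label_set <- function(image_id, height, width, annotations = list()) {
  stopifnot(is.character(image_id), length(image_id) == 1L,
            height >= 1, width >= 1)
  for (a in annotations) {
    if (!inherits(a, "nucleus_annotation"))
      stop("annotations must be nucleus_annotation objects")
    bb <- polygon_bbox(a$polygon)
    if (bb[1] < -1e-9 || bb[2] < -1e-9 || bb[3] > width + 1e-9 || bb[4] > height + 1e-9)
      stop(sprintf("annotation polygon outside image bounds in '%s'", image_id))
  }
  structure(list(image_id = image_id, height = as.integer(height),
                 width = as.integer(width), annotations = annotations),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  tab <- table(factor(vapply(x$annotations, `[[`, "", "cls"), levels = .CLASSES))
  cat(sprintf("<label_set> %s (%dx%d): %d nuclei [%s]\n", x$image_id,
              x$width, x$height, length(x$annotations),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
print.nucleus_annotation <- function(x, ...) {
  cat(sprintf("<nucleus_annotation> %s, %d vertices\n", x$cls, nrow(x$polygon)))
  invisible(x)
}

label_classes <- function(ls) vapply(ls$annotations, `[[`, "", "cls")

#' Count annotations per class
#'
#' @param x A `label_set` or a list of them.
#' @return Named integer vector over the three classes.
#' @export
class_counts <- function(x) {
  if (inherits(x, "label_set")) x <- list(x)
  cls <- unlist(lapply(x, label_classes), use.names = FALSE)
  tab <- table(factor(cls, levels = .CLASSES))
  stats::setNames(as.integer(tab), .CLASSES)
}
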