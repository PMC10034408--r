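# LabelMe-style JSON (one file per image) and aggregate COCO-JSON export.

#' Read a LabelMe-style annotation file
#'
#' Expects the LabelMe polygon dialect: top-level `imagePath`, `imageHeight`,
#' `imageWidth` and `shapes`, each shape carrying `label`, `points` and
#' `shape_type = "polygon"`. Class labels are matched case-insensitively.
#'
#' @param path Path to a JSON file.
#' @return A [label_set()].
#' @export
read_labelme <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop(sprintf("malformed JSON in %s: %s",
                                                  path, conditionMessage(e))))
  for (f in c("imagePath", "imageHeight", "imageWidth"))
    if (is.null(js[[f]])) stop(sprintf("%s: missing field '%s'", path, f))
  anns <- lapply(seq_along(js$shapes), function(i) {
    sh <- js$shapes[[i]]
    if (!is.null(sh$shape_type) && !identical(sh$shape_type, "polygon"))
      stop(sprintf("%s: shape %d has unsupported shape_type '%s'",
                   path, i, sh$shape_type))
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || nrow(pts) < 3L)
      stop(sprintf("%s: shape %d ('%s') has fewer than 3 vertices",
                   path, i, sh$label))
    nucleus_annotation(pts, sh$label)
  })
  label_set(image_id = sub("\\.(png|tif|tiff|jpg)$", "", basename(js$imagePath)),
            height = js$imageHeight, width = js$imageWidth, annotations = anns)
}

#' Write a label set as LabelMe-style JSON
#'
#' Inverse of [read_labelme()]: vertex coordinates and class labels
#' round-trip exactly.
#'
#' @param labels A [label_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(labels, path) {
  shapes <- lapply(labels$annotations, function(a) {
    list(label = a$cls,
         points = lapply(seq_len(nrow(a$polygon)),
                         function(i) as.numeric(a$polygon[i, ])),
         shape_type = "polygon")
  })
  js <- list(imagePath = paste0(labels$image_id, ".png"),
             imageHeight = labels$height, imageWidth = labels$width,
             shapes = shapes)
  writeLines(jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Export label sets as a single COCO-JSON file
#'
#' Category ids are fixed as yin = 1, yin-yang = 2, yang = 3. Segmentations
#' are the flattened polygon vertex lists; `area` is the shoelace polygon
#' area and `bbox` the xywh bounding box.
#'
#' @param label_sets List of [label_set()] objects with unique image ids.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_coco <- function(label_sets, path) {
  ids <- vapply(label_sets, `[[`, "", "image_id")
  if (anyDuplicated(ids)) stop("duplicate image ids in COCO export")
  images <- lapply(seq_along(label_sets), function(i) {
    ls <- label_sets[[i]]
    list(id = i, file_name = paste0(ls$image_id, ".png"),
         height = ls$height, width = ls$width)
  })
  annotations <- list(); k <- 0L
  for (i in seq_along(label_sets)) {
    for (a in label_sets[[i]]$annotations) {
      k <- k + 1L
      bb <- polygon_bbox(a$polygon)
      annotations[[k]] <- list(
        id = k, image_id = i,
        category_id = match(a$cls, .CLASSES),
        segmentation = list(as.numeric(t(a$polygon))),
        area = abs(polygon_area(a$polygon)),
        bbox = c(bb[1], bb[2], bb[3] - bb[1], bb[4] - bb[2]),
        iscrowd = 0L)
    }
  }
  coco <- list(
    images = images,
    annotations = annotations,
    categories = lapply(seq_along(.CLASSES), function(i)
      list(id = i, name = .CLASSES[i], supercategory = "nucleus")))
  writeLines(jsonlite::toJSON(coco, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a COCO-JSON file back into label sets
#'
#' Reads the dialect written by [export_coco()] (polygon segmentations,
#' category ids 1-3).
#'
#' @param path COCO-JSON file path.
#' @return List of [label_set()] objects.
#' @export
read_coco <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cats <- vapply(js$categories, function(ct) ct$name, "")
  anns_by_img <- split(js$annotations,
                       vapply(js$annotations, function(a) a$image_id, 1))
  lapply(js$images, function(im) {
    anns <- anns_by_img[[as.character(im$id)]]
    al <- lapply(anns, function(a) {
      seg <- as.numeric(unlist(a$segmentation[[1]]))
      poly <- matrix(seg, ncol = 2, byrow = TRUE)
      nucleus_annotation(poly, cats[[a$category_id]], validate = FALSE)
    })
    label_set(sub("\\.png$", "", im$file_name), im$height, im$width,
              if (is.null(al)) list() else al)
  })
}
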