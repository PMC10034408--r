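test_that("LabelMe write/read round-trips coordinates and classes exactly", {
  poly1 <- rbind(c(1.5, 2.25), c(10, 2), c(6, 9.75))
  poly2 <- rbind(c(20, 20), c(30, 22), c(28, 31), c(19, 29))
  ls <- label_set("img_a", 64, 64, list(
    nucleus_annotation(poly1, "yin"),
    nucleus_annotation(poly2, "yang"),
    nucleus_annotation(poly2 + 15, "yin-yang")))
  path <- withr::local_tempfile(fileext = ".json")
  write_labelme(ls, path)
  back <- read_labelme(path)
  expect_identical(back$image_id, ls$image_id)
  expect_identical(back$annotations, ls$annotations)
})

test_that("class strings normalize case-insensitively and invalid shapes error", {
  path <- withr::local_tempfile(fileext = ".json")
  js <- list(imagePath = "x.png", imageHeight = 32, imageWidth = 32,
             shapes = list(list(label = "Yang",
                                points = list(c(1, 1), c(9, 1), c(5, 8)),
                                shape_type = "polygon")))
  writeLines(jsonlite::toJSON(js, auto_unbox = TRUE), path)
  expect_identical(read_labelme(path)$annotations[[1]]$cls, "yang")

  js$shapes[[1]]$label <- "mystery"
  writeLines(jsonlite::toJSON(js, auto_unbox = TRUE), path)
  expect_error(read_labelme(path), "unknown nucleus class")

  js$shapes[[1]]$label <- "yin"
  js$shapes[[1]]$points <- list(c(1, 1), c(9, 1))
  writeLines(jsonlite::toJSON(js, auto_unbox = TRUE), path)
  expect_error(read_labelme(path), "fewer than 3 vertices")

  writeLines("{not json", path)
  expect_error(read_labelme(path), "malformed JSON")
})

test_that("COCO export counts records, fixes category ids and preserves raster area", {
  tri <- rbind(c(2, 2), c(12, 2), c(7, 11))
  ls1 <- label_set("im1", 32, 32, list(nucleus_annotation(tri, "yin"),
                                       nucleus_annotation(tri + 14, "yang")))
  ls2 <- label_set("im2", 32, 32, list(nucleus_annotation(tri, "yin-yang"),
                                       nucleus_annotation(tri + c(10, 0), "yang"),
                                       nucleus_annotation(tri + c(0, 14), "yin")))
  path <- withr::local_tempfile(fileext = ".json")
  export_coco(list(ls1, ls2), path)
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(js$images, 2L)
  expect_length(js$annotations, 5L)
  expect_length(js$categories, 3L)
  expect_identical(vapply(js$categories, `[[`, "", "name"), cell_classes())
  expect_identical(js$annotations[[2]]$category_id, 3L)

  back <- read_coco(path)
  m0 <- polygon_to_mask(tri, 32, 32)
  m1 <- polygon_to_mask(back[[1]]$annotations[[1]]$polygon, 32, 32)
  expect_identical(sum(m1), sum(m0))

  export_coco(list(), withr::local_tempfile(fileext = ".json")) |>
    jsonlite::fromJSON(simplifyVector = FALSE) -> empty
  expect_length(empty$annotations, 0L)

  expect_error(export_coco(list(ls1, ls1), path), "duplicate image ids")
})

test_that("polygon_to_mask matches the analytic square and full-frame cases", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_identical(sum(polygon_to_mask(sq, 20, 20)), 100L)
  full <- rbind(c(0, 0), c(16, 0), c(16, 12), c(0, 12))
  expect_true(all(polygon_to_mask(full, 12, 16)))
})

test_that("polygon_to_mask equals brute-force even-odd on random polygons", {
  set.seed(404)
  for (k in seq_len(100)) {
    poly <- random_star_polygon(15, 15)
    expect_identical(polygon_to_mask(poly, 15, 15),
                     brute_polygon_mask(poly, 15, 15))
  }
  tri <- rbind(c(0.3, 0.7), c(13.2, 4.1), c(5.5, 12.9))
  expect_identical(polygon_to_mask(tri, 14, 14), brute_polygon_mask(tri, 14, 14))
})

test_that("mask_to_polygon inverts rasterization exactly for convex masks", {
  set.seed(77)
  for (k in seq_len(15)) {
    # random filled ellipses: convex, so the contract is exact recovery
    cx <- runif(1, 8, 12); cy <- runif(1, 8, 12)
    a <- runif(1, 2.5, 6); b <- runif(1, 2.5, 6); phi <- runif(1, 0, pi)
    xs <- matrix(rep(seq_len(20) - 0.5, each = 20), 20, 20)
    ys <- matrix(rep(seq_len(20) - 0.5, times = 20), 20, 20)
    xr <- (xs - cx) * cos(phi) + (ys - cy) * sin(phi)
    yr <- -(xs - cx) * sin(phi) + (ys - cy) * cos(phi)
    m <- (xr / a)^2 + (yr / b)^2 <= 1
    if (!any(m)) next
    expect_identical(polygon_to_mask(mask_to_polygon(m), 20, 20), m)
  }
  expect_error(mask_to_polygon(matrix(FALSE, 4, 4)), "empty")
})

test_that("mask_to_polygon recovers irregular star masks near-losslessly", {
  set.seed(78)
  for (k in seq_len(15)) {
    m <- polygon_to_mask(random_star_polygon(20, 20), 20, 20)
    if (sum(m) < 5) next
    m2 <- polygon_to_mask(mask_to_polygon(m), 20, 20)
    expect_gte(sum(m & m2) / sum(m | m2), 0.95)
  }
})

test_that("flip augmentation is an involution on image and polygons", {
  f <- generate_field(scene_spec(seed = 3, n_cells = 12))
  a1 <- augment(f$image, f$labels, seed = 5, family = "flip")
  a2 <- augment(a1$image, a1$labels, seed = 5, family = "flip")
  expect_identical(a2$transform$axis, a1$transform$axis)
  expect_equal(a2$image, f$image)
  expect_equal(a2$labels$annotations, f$labels$annotations, tolerance = 1e-12)
})

test_that("contrast augmentation leaves annotations untouched", {
  f <- generate_field(scene_spec(seed = 4, n_cells = 10))
  a <- augment(f$image, f$labels, seed = 11, family = "contrast")
  expect_identical(a$labels, f$labels)
  expect_false(identical(a$image, f$image))
})

test_that("affine augmentation maps polygon vertices by the sampled matrix", {
  # one small nucleus at the centre: never clipped by the mild affine family,
  # so the logged (A, center, t) must reproduce every vertex in closed form
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  poly <- cbind(128 + 8 * cos(th), 128 + 8 * sin(th))
  labels <- label_set("ctr", 256, 256, list(nucleus_annotation(poly, "yang")))
  img <- array(0.9, c(256, 256, 3))
  for (s in c(21, 22, 23)) {
    a <- augment(img, labels, seed = s, family = "affine")
    tr <- a$transform
    mapped <- t(tr$A %*% (t(poly) - tr$center) + tr$center + c(tr$tx, tr$ty))
    expect_length(a$labels$annotations, 1L)
    expect_lt(max(abs(mapped - a$labels$annotations[[1]]$polygon)), 1e-6)
    expect_identical(a$labels$annotations[[1]]$cls, "yang")
  }
})

test_that("augmentation picks exactly one family per seed and preserves labels", {
  f <- generate_field(scene_spec(seed = 8, n_cells = 8))
  fams <- vapply(1:12, function(s)
    suppressWarnings(augment(f$image, f$labels, seed = s))$transform$family, "")
  expect_true(all(fams %in% c("flip", "affine", "contrast")))
  expect_gte(length(unique(fams)), 2L)
  for (s in 1:6) {
    a <- suppressWarnings(augment(f$image, f$labels, seed = s))
    cls_in <- table(vapply(f$labels$annotations, `[[`, "", "cls"))
    cls_out <- table(vapply(a$labels$annotations, `[[`, "", "cls"))
    expect_true(all(names(cls_out) %in% names(cls_in)))
    if (a$transform$family != "affine")
      expect_identical(length(a$labels$annotations), length(f$labels$annotations))
  }
})
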