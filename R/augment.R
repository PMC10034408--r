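# Three-way training augmentation: flip/mirror, mild affine, contrast.
# One family is chosen uniformly per call; geometric transforms are applied
# identically to image and polygons, contrast leaves annotations untouched.

#' Augment an image and its annotations
#'
#' Applies exactly one of three transform families, chosen uniformly at
#' random from `seed`: flip/mirror (horizontal or vertical, equiprobable),
#' a mild affine map (rotation within ±25°, isotropic scale 0.8–1.2, shear
#' within ±8°, translation within ±10% of the field, about the image
#' center), or a contrast change (gamma 0.7–1.4 or linear contrast ±30%).
#' Class labels are never changed. Polygons mapped partially out of the
#' field by an affine are clipped to the field and dropped (with a warning)
#' when the clipped raster area falls below 20% of the original.
#'
#' @param image Numeric `h x w x 3` array in `[0, 1]`.
#' @param labels Matching [label_set()].
#' @param seed Integer seed controlling the family and parameter draws.
#' @param family Optional override: `"flip"`, `"affine"` or `"contrast"`.
#' @return List with elements `image`, `labels` and `transform` (the family
#'   and sampled parameters, for audit).
#' @export
augment <- function(image, labels, seed, family = NULL) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h != labels$height || w != labels$width)
    stop("image and label_set dimensions disagree")
  res <- with_seed(seed, {
    fam <- if (is.null(family)) sample(c("flip", "affine", "contrast"), 1L)
    else match.arg(family, c("flip", "affine", "contrast"))
    switch(fam,
           flip = aug_flip(image, labels),
           affine = aug_affine(image, labels),
           contrast = aug_contrast(image, labels))
  })
  res
}

aug_flip <- function(image, labels) {
  axis <- sample(c("horizontal", "vertical"), 1L)
  w <- labels$width; h <- labels$height
  if (axis == "horizontal") {
    img2 <- image[, dim(image)[2]:1, , drop = FALSE]
    map <- function(p) cbind(w - p[, 1], p[, 2])
  } else {
    img2 <- image[dim(image)[1]:1, , , drop = FALSE]
    map <- function(p) cbind(p[, 1], h - p[, 2])
  }
  anns <- lapply(labels$annotations, function(a)
    nucleus_annotation(map(a$polygon), a$cls, validate = FALSE))
  list(image = img2,
       labels = label_set(labels$image_id, h, w, anns),
       transform = list(family = "flip", axis = axis))
}

aug_affine <- function(image, labels) {
  h <- labels$height; w <- labels$width
  theta <- runif(1, -25, 25) * pi / 180
  s <- runif(1, 0.8, 1.2)
  shear <- runif(1, -8, 8) * pi / 180
  tx <- runif(1, -0.1, 0.1) * w
  ty <- runif(1, -0.1, 0.1) * h
  # forward map: p' = A (p - c) + c + t
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2) %*%
    matrix(c(s, 0, 0, s), 2) %*% matrix(c(1, 0, tan(shear), 1), 2)
  ctr <- c(w / 2, h / 2)
  img2 <- warp_affine(image, A, ctr, c(tx, ty))
  anns <- list(); dropped <- 0L
  for (a in labels$annotations) {
    p2 <- t(A %*% (t(a$polygon) - ctr) + ctr + c(tx, ty))
    clipped <- clip_polygon_rect(p2, w, h)
    if (nrow(clipped) < 3L) { dropped <- dropped + 1L; next }
    if (abs(polygon_area(clipped)) < 0.2 * abs(polygon_area(a$polygon))) {
      dropped <- dropped + 1L; next
    }
    anns[[length(anns) + 1L]] <- nucleus_annotation(clipped, a$cls, validate = FALSE)
  }
  if (dropped > 0L)
    warning(sprintf("augment: %d annotation(s) dropped (mapped outside field)", dropped))
  list(image = img2,
       labels = label_set(labels$image_id, h, w, anns),
       transform = list(family = "affine", theta = theta, scale = s,
                        shear = shear, tx = tx, ty = ty, A = A, center = ctr))
}

aug_contrast <- function(image, labels) {
  mode <- sample(c("gamma", "linear"), 1L)
  if (mode == "gamma") {
    g <- runif(1, 0.7, 1.4)
    img2 <- image ^ g
    params <- list(family = "contrast", mode = "gamma", gamma = g)
  } else {
    f <- runif(1, 0.7, 1.3)
    img2 <- pmin(pmax(0.5 + (image - 0.5) * f, 0), 1)
    params <- list(family = "contrast", mode = "linear", factor = f)
  }
  list(image = img2, labels = labels, transform = params)
}

# inverse-mapped bilinear warp; out-of-field samples take the pale
# background tone used by the field generator
warp_affine <- function(image, A, ctr, tvec, fill = c(0.93, 0.90, 0.94)) {
  h <- dim(image)[1]; w <- dim(image)[2]
  Ainv <- solve(A)
  xo <- rep(seq_len(w) - 0.5, each = h)
  yo <- rep(seq_len(h) - 0.5, times = w)
  src <- Ainv %*% rbind(xo - ctr[1] - tvec[1], yo - ctr[2] - tvec[2])
  xs <- src[1, ] + ctr[1]; ys <- src[2, ] + ctr[2]
  # bilinear sample at pixel-center grid
  cx <- xs - 0.5; cy <- ys - 0.5
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  out <- array(0, dim(image))
  inb <- function(xx, yy) xx >= 0 & xx <= w - 1 & yy >= 0 & yy <= h - 1
  for (ch in seq_len(dim(image)[3])) {
    plane <- image[, , ch]
    gv <- function(xx, yy) {
      v <- rep(fill[ch], length(xx))
      ok <- inb(xx, yy)
      v[ok] <- plane[cbind(yy[ok] + 1L, xx[ok] + 1L)]
      v
    }
    val <- gv(x0, y0) * (1 - fx) * (1 - fy) + gv(x0 + 1, y0) * fx * (1 - fy) +
      gv(x0, y0 + 1) * (1 - fx) * fy + gv(x0 + 1, y0 + 1) * fx * fy
    ool <- !inb(pmin(pmax(x0, 0), w - 1), pmin(pmax(y0, 0), h - 1)) &
      !inb(x0, y0) & !inb(x0 + 1, y0 + 1)
    val[ool] <- fill[ch]
    out[, , ch] <- matrix(val, nrow = h)
  }
  out
}
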