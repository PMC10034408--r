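# Polygon <-> mask geometry.
#
# Conventions (fixed package-wide): 0-based pixel coordinates, x rightward
# (columns), y downward (rows); polygon vertices live at pixel-corner
# resolution (floats allowed); the pixel in column cx, row cy (0-based) has
# its center at (cx + 0.5, cy + 0.5). Masks are logical matrices indexed
# [row, col] = [y + 1, x + 1].

#' Rasterize a polygon to a binary mask
#'
#' A pixel is set if and only if its center falls inside the polygon under
#' the even-odd rule. This pixel-center convention is unambiguous and is
#' brute-force verifiable by per-pixel point-in-polygon tests.
#'
#' @param polygon Numeric matrix with columns x, y (0-based pixel
#'   coordinates), at least 3 rows.
#' @param height,width Mask dimensions in pixels.
#' @return Logical `height x width` matrix.
#' @export
polygon_to_mask <- function(polygon, height, width) {
  polygon <- as_polygon(polygon)
  mask <- matrix(FALSE, nrow = height, ncol = width)
  n <- nrow(polygon)
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  idx <- c(2:n, 1)
  x2 <- x1[idx]; y2 <- y1[idx]
  lo <- pmin(y1, y2); hi <- pmax(y1, y2)
  r0 <- max(1L, floor(min(lo) + 0.5) + 1L)
  r1 <- min(height, ceiling(max(hi) + 0.5) - 1L)
  if (r0 > r1) return(mask)
  for (r in r0:r1) {
    yc <- r - 0.5
    sel <- yc >= lo & yc < hi            # half-open rule: horizontal edges never cross
    if (!any(sel)) next
    xc <- sort(x1[sel] + (yc - y1[sel]) * (x2[sel] - x1[sel]) / (y2[sel] - y1[sel]))
    for (i in seq(1L, length(xc) - 1L, by = 2L)) {
      c1 <- max(1L, floor(xc[i] + 0.5) + 1L)        # first col with center > xc[i]
      c2 <- min(width, ceiling(xc[i + 1] + 0.5) - 1L)  # last col with center < xc[i+1]
      if (c1 <= c2) mask[r, c1:c2] <- TRUE
    }
  }
  mask
}

#' Trace the outer contour of a binary mask as a polygon
#'
#' Traces the boundary between inside and outside pixels along pixel corners,
#' so that rasterizing the returned polygon with [polygon_to_mask()] recovers
#' the mask exactly for any hole-free connected mask (convex or not). When
#' the mask has several connected components the largest-area contour is
#' returned.
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of x, y vertices (pixel-corner coordinates).
#' @export
mask_to_polygon <- function(mask) {
  if (!any(mask)) stop("mask_to_polygon: mask is empty")
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inside <- which(pad, arr.ind = TRUE)
  r <- inside[, 1]; c <- inside[, 2]
  x <- c - 2L; y <- r - 2L                      # 0-based pixel coords in mask
  up    <- !pad[cbind(r - 1L, c)]
  right <- !pad[cbind(r, c + 1L)]
  down  <- !pad[cbind(r + 1L, c)]
  left  <- !pad[cbind(r, c - 1L)]
  # directed boundary edges (interior kept on the right while walking)
  sx <- c(x[up],        x[right] + 1L, x[down] + 1L, x[left])
  sy <- c(y[up],        y[right],      y[down] + 1L, y[left] + 1L)
  ex <- c(x[up] + 1L,   x[right] + 1L, x[down],      x[left])
  ey <- c(y[up],        y[right] + 1L, y[down] + 1L, y[left])
  key <- function(px, py) px * (h + 3L) + py
  skey <- key(sx, sy)
  used <- rep(FALSE, length(sx))
  # map start-corner -> edge indices (a corner can host 2 outgoing edges)
  ord <- order(skey)
  runs <- rle(skey[ord])
  first <- c(1L, head(cumsum(runs$lengths), -1L) + 1L)
  lookup_env <- new.env(hash = TRUE, size = length(runs$values))
  for (i in seq_along(runs$values)) {
    assign(as.character(runs$values[i]),
           ord[first[i]:(first[i] + runs$lengths[i] - 1L)], envir = lookup_env)
  }
  trace_from <- function(start) {
    verts_x <- integer(0); verts_y <- integer(0)
    cur <- start
    repeat {
      used[cur] <<- TRUE
      verts_x <- c(verts_x, sx[cur]); verts_y <- c(verts_y, sy[cur])
      nk <- as.character(key(ex[cur], ey[cur]))
      cand <- get0(nk, envir = lookup_env, ifnotfound = integer(0))
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      if (length(cand) > 1L) {
        # kissing-diagonal corner: turn toward the interior (y-down frame:
        # largest cross product) so the walk hugs the current component
        dx <- ex[cur] - sx[cur]; dy <- ey[cur] - sy[cur]
        cross <- dx * (ey[cand] - sy[cand]) - dy * (ex[cand] - sx[cand])
        cand <- cand[order(-cross)][1L]
      }
      cur <- cand
      if (sx[cur] == verts_x[1L] && sy[cur] == verts_y[1L]) break
    }
    cbind(x = verts_x, y = verts_y)
  }
  best <- NULL; best_area <- -1
  while (any(!used)) {
    poly <- trace_from(which(!used)[1L])
    a <- abs(polygon_area(poly))
    if (a > best_area) { best_area <- a; best <- poly }
  }
  simplify_collinear(best)
}

simplify_collinear <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(poly)
  prev <- poly[c(n, 1:(n - 1L)), , drop = FALSE]
  nxt <- poly[c(2:n, 1L), , drop = FALSE]
  cross <- (poly[, 1] - prev[, 1]) * (nxt[, 2] - poly[, 2]) -
    (poly[, 2] - prev[, 2]) * (nxt[, 1] - poly[, 1])
  keep <- abs(cross) > 1e-12
  if (sum(keep) < 3L) return(poly)
  poly[keep, , drop = FALSE]
}

#' Signed polygon area (shoelace)
#'
#' @param polygon Vertex matrix (x, y).
#' @return Signed area; positive for counter-clockwise order in a y-down
#'   coordinate frame's mathematical sense.
#' @export
polygon_area <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  n <- length(x)
  idx <- c(2:n, 1)
  sum(x * y[idx] - x[idx] * y) / 2
}

as_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("polygon must be a matrix of >= 3 (x, y) vertices")
  storage.mode(polygon) <- "double"
  polygon
}

# TRUE if the closed polygon has no two non-adjacent edges crossing.
polygon_is_simple <- function(polygon) {
  p <- as_polygon(polygon)
  n <- nrow(p)
  seg_int <- function(a, b, c, d) {
    o <- function(p1, p2, p3)
      sign((p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1]))
    o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
    (o1 != o2 && o3 != o4)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i + 2L) next                 # shared-vertex neighbours
      if (i == 1L && j == n) next          # closing edge adjoins the first
      a <- p[i, ]; b <- p[i %% n + 1L, ]
      cc <- p[j, ]; d <- p[j %% n + 1L, ]
      if (seg_int(a, b, cc, d)) return(FALSE)
    }
  }
  TRUE
}

# bbox as c(x0, y0, x1, y1) in 0-based corner coords
polygon_bbox <- function(polygon) {
  c(min(polygon[, 1]), min(polygon[, 2]), max(polygon[, 1]), max(polygon[, 2]))
}

# Rasterized representation restricted to the polygon's bounding box:
# list(x0, y0 integer pixel offsets, mask submatrix). Used for fast IoU.
polygon_submask <- function(polygon, height, width) {
  bb <- polygon_bbox(polygon)
  cx0 <- max(0L, floor(bb[1])); cy0 <- max(0L, floor(bb[2]))
  cx1 <- min(width - 1L, ceiling(bb[3])); cy1 <- min(height - 1L, ceiling(bb[4]))
  if (cx0 > cx1 || cy0 > cy1)
    return(list(x0 = 0L, y0 = 0L, mask = matrix(FALSE, 0, 0)))
  shifted <- cbind(polygon[, 1] - cx0, polygon[, 2] - cy0)
  sub <- polygon_to_mask(shifted, cy1 - cy0 + 1L, cx1 - cx0 + 1L)
  list(x0 = as.integer(cx0), y0 = as.integer(cy0), mask = sub)
}

submask_iou <- function(a, b) {
  inter <- submask_intersection(a, b)
  if (inter == 0) return(0)
  inter / (sum(a$mask) + sum(b$mask) - inter)
}

submask_intersection <- function(a, b) {
  ax1 <- a$x0 + ncol(a$mask) - 1L; ay1 <- a$y0 + nrow(a$mask) - 1L
  bx1 <- b$x0 + ncol(b$mask) - 1L; by1 <- b$y0 + nrow(b$mask) - 1L
  x0 <- max(a$x0, b$x0); y0 <- max(a$y0, b$y0)
  x1 <- min(ax1, bx1); y1 <- min(ay1, by1)
  if (x0 > x1 || y0 > y1) return(0)
  sa <- a$mask[(y0 - a$y0 + 1L):(y1 - a$y0 + 1L), (x0 - a$x0 + 1L):(x1 - a$x0 + 1L), drop = FALSE]
  sb <- b$mask[(y0 - b$y0 + 1L):(y1 - b$y0 + 1L), (x0 - b$x0 + 1L):(x1 - b$x0 + 1L), drop = FALSE]
  sum(sa & sb)
}

#' Intersection-over-union of two polygons
#'
#' Computed on the pixel-center rasterization of both polygons, the same
#' convention used for detection-truth matching.
#'
#' @param poly_a,poly_b Vertex matrices.
#' @param height,width Raster frame dimensions.
#' @return IoU in `[0, 1]`.
#' @export
polygon_iou <- function(poly_a, poly_b, height, width) {
  submask_iou(polygon_submask(as_polygon(poly_a), height, width),
              polygon_submask(as_polygon(poly_b), height, width))
}

# Sutherland-Hodgman clip of a polygon to the rectangle [0,w] x [0,h]
clip_polygon_rect <- function(polygon, width, height) {
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prv <- pts[if (i == 1L) n else i - 1L, ]
      ci <- inside(cur); pi <- inside(prv)
      if (ci) {
        if (!pi) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pi) out <- rbind(out, intersect(prv, cur))
    }
    out
  }
  ixx <- function(bound, coord) function(p, q) {
    t <- (bound - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  p <- as.matrix(polygon)
  p <- clip_edge(p, function(v) v[1] >= 0, ixx(0, 1))
  p <- clip_edge(p, function(v) v[1] <= width, ixx(width, 1))
  p <- clip_edge(p, function(v) v[2] >= 0, ixx(0, 2))
  p <- clip_edge(p, function(v) v[2] <= height, ixx(height, 2))
  p
}
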