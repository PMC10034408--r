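# Pluggable nucleus detector with a classical reference backend:
# stain-intensity thresholding (Otsu on inverted luminance), distance
# transform + watershed splitting of touching blobs, per-blob shape and
# intensity features, and a multinomial logistic head trained with
# inverse-frequency class weights (the weighted cross-entropy objective).

#' Detector configuration
#'
#' @param min_area Minimum blob area in pixels; smaller components are
#'   treated as noise.
#' @param max_lum Maximum mean luminance of a blob; brighter components
#'   (background speckle, pale cytoplasm) are discarded. Stained nuclei are
#'   substantially darker.
#' @param ws_tolerance Watershed tolerance (in distance-map units) when
#'   splitting touching blobs; higher values merge more aggressively.
#' @param weight_cap Cap for inverse-frequency class weights.
#' @param oversample_target Abnormal-image fraction targeted by
#'   [oversample_positives()] before feature harvesting; 0 disables.
#' @param augment Double the training set with one random augmentation per
#'   image (see [augment()]).
#' @param nms_iou Non-maximum-suppression IoU threshold.
#' @param decay L2 weight decay for the multinomial head; a small ridge
#'   penalty keeps the class probabilities calibrated when the training
#'   classes are linearly separable.
#' @param maxit Optimizer iteration cap for the multinomial head.
#' @return Named list of class `detector_config`.
#' @export
detector_config <- function(min_area = 20, max_lum = 0.8, ws_tolerance = 3,
                            weight_cap = 100, oversample_target = 0.25,
                            augment = FALSE, nms_iou = 0.5, decay = 1e-3,
                            maxit = 300) {
  structure(list(min_area = min_area, max_lum = max_lum,
                 ws_tolerance = ws_tolerance, weight_cap = weight_cap,
                 oversample_target = oversample_target, augment = augment,
                 nms_iou = nms_iou, decay = decay, maxit = maxit),
            class = "detector_config")
}

.FEATURE_NAMES <- c("area", "eq_diameter", "mean_lum", "min_lum",
                    "eccentricity", "solidity", "roughness", "radius_cv")

luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# candidate nucleus blobs: list of list(submask, features)
segment_blobs <- function(image, config = detector_config()) {
  lum <- luminance(image)
  inv <- 1 - lum
  thr <- EBImage::otsu(EBImage::Image(inv), range = c(0, 1))
  fg <- inv > thr
  if (!any(fg)) return(list())
  dm <- EBImage::distmap(EBImage::Image(fg))
  ws <- EBImage::watershed(dm, tolerance = config$ws_tolerance, ext = 1)
  labm <- EBImage::imageData(ws)
  nlab <- max(labm)
  out <- list()
  for (l in seq_len(nlab)) {
    idx <- which(labm == l, arr.ind = TRUE)
    if (nrow(idx) < config$min_area) next
    lv <- lum[idx]
    if (mean(lv) > config$max_lum) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- TRUE
    sm <- list(x0 = c0 - 1L, y0 = r0 - 1L, mask = sub)
    out[[length(out) + 1L]] <- list(submask = sm,
                                    features = blob_features(sm, idx, lv))
  }
  out
}

# shape + intensity descriptors for one blob
blob_features <- function(sm, idx, lum_vals) {
  area <- nrow(idx)
  # rectilinear perimeter: count inside->outside pixel edges
  pad <- matrix(FALSE, nrow(sm$mask) + 2L, ncol(sm$mask) + 2L)
  pad[2:(nrow(sm$mask) + 1L), 2:(ncol(sm$mask) + 1L)] <- sm$mask
  ins <- which(pad, arr.ind = TRUE)
  perim <- sum(!pad[cbind(ins[, 1] - 1L, ins[, 2])]) +
    sum(!pad[cbind(ins[, 1] + 1L, ins[, 2])]) +
    sum(!pad[cbind(ins[, 1], ins[, 2] - 1L)]) +
    sum(!pad[cbind(ins[, 1], ins[, 2] + 1L)])
  x <- idx[, 2] - 0.5; y <- idx[, 1] - 0.5
  mx <- mean(x); my <- mean(y)
  mxx <- mean((x - mx)^2); myy <- mean((y - my)^2); mxy <- mean((x - mx) * (y - my))
  tr <- mxx + myy; dt <- sqrt(max(0, (mxx - myy)^2 + 4 * mxy^2))
  l1 <- (tr + dt) / 2; l2 <- max((tr - dt) / 2, 1e-9)
  ecc <- sqrt(max(0, 1 - l2 / l1))
  hull <- grDevices::chull(x, y)
  hull_area <- abs(polygon_area(cbind(x[hull], y[hull])))
  solidity <- min(1, area / max(hull_area, 1e-9))
  rr <- sqrt((x - mx)^2 + (y - my)^2)
  c(area = area,
    eq_diameter = 2 * sqrt(area / pi),
    mean_lum = mean(lum_vals),
    min_lum = min(lum_vals),
    eccentricity = ecc,
    solidity = solidity,
    roughness = perim^2 / (4 * pi * area),
    radius_cv = stats::sd(rr) / max(mean(rr), 1e-9))
}

#' Train the reference nucleus detector
#'
#' Segments every training field, assigns each candidate blob the class of
#' the ground-truth nucleus it overlaps (IoU >= 0.5), and fits a
#' multinomial logistic classifier on standardized blob features with
#' inverse-frequency case weights, i.e. the class-weighted cross-entropy
#' objective. Training is deterministic given `seed`.
#'
#' @param fields List of `list(image, labels)` training elements.
#' @param config A [detector_config()].
#' @param seed Integer seed (drives oversampling order and any
#'   augmentation draws).
#' @param init Optional previously trained detector used to warm-start the
#'   optimizer (active-learning rounds continue from the prior model).
#' @return Object of class `cyto_detector`.
#' @export
train_detector <- function(fields, config = detector_config(), seed = 1L,
                           init = NULL) {
  stopifnot(length(fields) >= 1L)
  if (config$oversample_target > 0) {
    fields <- tryCatch(oversample_positives(fields, config$oversample_target),
                       error = function(e) fields)
  }
  if (isTRUE(config$augment)) {
    n0 <- length(fields)
    for (i in seq_len(n0)) {
      au <- suppressWarnings(
        augment(fields[[i]]$image, fields[[i]]$labels,
                seed = derive_seed(seed, "augment", i)))
      fields[[n0 + i]] <- list(image = au$image, labels = au$labels)
    }
  }
  feats <- list(); labs <- character(0)
  for (f in fields) {
    blobs <- segment_blobs(f$image, config)
    if (length(blobs) == 0L) next
    h <- f$labels$height; w <- f$labels$width
    tmasks <- lapply(f$labels$annotations,
                     function(a) polygon_submask(a$polygon, h, w))
    tcls <- label_classes(f$labels)
    for (b in blobs) {
      best <- 0; best_c <- NA_character_
      for (j in seq_along(tmasks)) {
        iou <- submask_iou(b$submask, tmasks[[j]])
        if (iou > best) { best <- iou; best_c <- tcls[j] }
      }
      if (best >= 0.5) {
        feats[[length(feats) + 1L]] <- b$features
        labs <- c(labs, best_c)
      }
    }
  }
  if (length(feats) == 0L)
    stop("train_detector: no training blobs matched ground truth")
  X <- do.call(rbind, feats)
  colnames(X) <- .FEATURE_NAMES
  present <- intersect(.CLASSES, unique(labs))
  counts <- table(factor(labs, levels = present))
  if (length(present) < 3L)
    warning(sprintf("training set contains only class(es): %s",
                    paste(present, collapse = ", ")))
  cw <- compute_class_weights(as.numeric(counts) + 0, cap = config$weight_cap)
  names(cw) <- present
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd); scl[scl < 1e-9] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  fit <- NULL
  if (length(present) > 1L) {
    y <- factor(labs, levels = present)
    dat <- data.frame(Xs, y = y, check.names = FALSE)
    wts_case <- cw[as.character(y)]
    n_wts <- (ncol(Xs) + 2L) * (length(present) - 0L)
    start <- NULL
    if (!is.null(init) && !is.null(init$fit) &&
        identical(init$classes, present)) {
      start <- init$fit$wts
    }
    fit <- with_seed(derive_seed(seed, "multinom"), {
      if (!is.null(start))
        nnet::multinom(y ~ ., data = dat, weights = wts_case, trace = FALSE,
                       maxit = config$maxit, decay = config$decay, Wts = start)
      else
        nnet::multinom(y ~ ., data = dat, weights = wts_case, trace = FALSE,
                       maxit = config$maxit, decay = config$decay)
    })
  }
  model <- list(fit = fit, classes = present, class_weights = cw,
                center = ctr, scale = scl, config = config,
                config_digest = config_digest(config, seed),
                interface_version = 1L, trained = TRUE)
  class(model) <- "cyto_detector"
  model
}

config_digest <- function(config, seed) {
  s <- paste(names(unlist(config)), unlist(config), seed, collapse = ";")
  sprintf("%08x", derive_seed(0L, s))
}

#' @export
print.cyto_detector <- function(x, ...) {
  cat(sprintf("<cyto_detector> classes: %s | weights: %s | digest %s\n",
              paste(x$classes, collapse = ", "),
              paste(sprintf("%.3g", x$class_weights), collapse = ", "),
              x$config_digest))
  invisible(x)
}

#' Detect and classify nuclei in one field
#'
#' Runs segmentation, scores every candidate blob with the fitted
#' multinomial head, traces each blob's contour as a polygon, and applies
#' score-descending non-maximum suppression so no two retained detections
#' exceed the configured IoU.
#'
#' @param model A trained [train_detector()] model.
#' @param image `h x w x 3` array in `[0, 1]`.
#' @param image_id Identifier stamped on the detections.
#' @return List of detections, each `list(image_id, polygon, cls, score,
#'   prob)` with `prob` the full 3-class probability vector (absent classes
#'   carry probability 0) and `score = max(prob)`.
#' @export
detect <- function(model, image, image_id = "image") {
  if (!inherits(model, "cyto_detector") || !isTRUE(model$trained))
    stop("detect: model is not a trained cyto_detector")
  blobs <- segment_blobs(image, model$config)
  if (length(blobs) == 0L) return(list())
  X <- do.call(rbind, lapply(blobs, `[[`, "features"))
  colnames(X) <- .FEATURE_NAMES
  Xs <- scale(X, center = model$center, scale = model$scale)
  probs <- matrix(0, nrow(Xs), 3, dimnames = list(NULL, .CLASSES))
  if (is.null(model$fit)) {
    probs[, model$classes[1]] <- 1
  } else {
    pr <- predict(model$fit, newdata = data.frame(Xs, check.names = FALSE),
                  type = "probs")
    if (is.null(dim(pr))) {
      if (length(model$classes) == 2L && nrow(Xs) > 1L) {
        # two-class multinom returns P(second level) per row
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- model$classes
      } else if (length(model$classes) == 2L) {
        pr <- matrix(c(1 - pr, pr), nrow = 1,
                     dimnames = list(NULL, model$classes))
      } else {
        # single prediction row: named probability vector
        pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
      }
    }
    probs[, colnames(pr)] <- pr
  }
  dets <- lapply(seq_along(blobs), function(i) {
    p <- probs[i, ]
    cls <- .CLASSES[which.max(p)]
    poly <- mask_to_polygon(blobs[[i]]$submask$mask)
    poly[, 1] <- poly[, 1] + blobs[[i]]$submask$x0
    poly[, 2] <- poly[, 2] + blobs[[i]]$submask$y0
    list(image_id = image_id, polygon = poly,
         cls = cls, score = unname(max(p)), prob = p,
         .submask = blobs[[i]]$submask)
  })
  nms(dets, iou = model$config$nms_iou)
}

#' Non-maximum suppression over detections
#'
#' Score-descending greedy suppression (ties broken by lower index): a
#' detection overlapping an already-kept one above `iou` is dropped.
#'
#' @param detections List of detections carrying `.submask` or `polygon`.
#' @param iou Suppression threshold.
#' @return Filtered detection list (input order preserved).
#' @export
nms <- function(detections, iou = 0.5) {
  n <- length(detections)
  if (n <= 1L) return(detections)
  scores <- vapply(detections, `[[`, 0, "score")
  ord <- order(-scores, seq_len(n))
  keep <- logical(n)
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (submask_iou(detections[[i]]$.submask, detections[[j]]$.submask) > iou) {
        ok <- FALSE; break
      }
    }
    keep[i] <- ok
  }
  detections[keep]
}

#' Save / load a trained detector
#'
#' Single-file archive (RDS) containing the fitted head, feature scaling,
#' class weights and config digest; loading reproduces predictions
#' bit-identically.
#'
#' @param model A `cyto_detector`.
#' @param path File path.
#' @return `path` (save) or the restored model (load).
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "cyto_detector"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cyto_detector")) stop("not a cyto_detector archive")
  model
}
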