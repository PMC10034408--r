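# Seeded synthetic cytology: single-field images with ground-truth nucleus
# annotations, patient cohorts, and a simulated-pathologist revision oracle.

#' Scene specification for one synthetic cytology field
#'
#' Defines the field geometry, the class mixture and the class-conditional
#' nucleus morphology. Defaults encode the qualitative cytologic criteria of
#' the three-way taxonomy: yang nuclei are larger, darker-stained and more
#' irregular than yin-yang nuclei, which in turn exceed normal yin nuclei;
#' the nucleocytoplasmic-ratio proxy rises with lesion degree.
#'
#' @param field_size `c(width, height)` in pixels. 256 x 256 by default
#'   (desk scale); set `c(1024, 1024)` for full-scanner-resolution fields.
#' @param n_cells Number of nuclei to place.
#' @param class_mix Probability vector over (yin, yin-yang, yang); must sum
#'   to 1.
#' @param morphology Per-class list with `radius_mean`, `radius_sd` (px),
#'   `intensity_mean`, `intensity_sd` (0-255 stain scale, darker = more
#'   stained), `irregularity` in `[0, 1]` and `ncr` (nucleocytoplasmic-ratio
#'   proxy) in `(0, 1)`.
#' @param overlap_fraction Maximum tolerated pairwise bounding-disc IoU
#'   between nuclei; 0 (the default) forces disjoint nuclei.
#' @param seed Integer seed; everything drawn for the field derives from it.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(field_size = c(256, 256), n_cells = 40,
                       class_mix = c(yin = 0.90, `yin-yang` = 0.05, yang = 0.05),
                       morphology = default_morphology(),
                       overlap_fraction = 0, seed = 1L) {
  class_mix <- as.numeric(class_mix)
  if (length(class_mix) != 3L || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must be 3 nonnegative probabilities summing to 1")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  rm_ <- vapply(morphology, `[[`, 0, "radius_mean")
  im_ <- vapply(morphology, `[[`, 0, "intensity_mean")
  if (!(rm_[["yang"]] > rm_[["yin-yang"]] && rm_[["yin-yang"]] > rm_[["yin"]]))
    stop("morphology must satisfy yang > yin-yang > yin mean radius")
  if (!(im_[["yang"]] < im_[["yin"]]))
    stop("yang mean intensity must be darker (smaller) than yin")
  structure(list(field_size = as.integer(field_size), n_cells = as.integer(n_cells),
                 class_mix = stats::setNames(class_mix, .CLASSES),
                 morphology = morphology,
                 overlap_fraction = overlap_fraction, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default class-conditional nucleus morphology
#'
#' Radii and stain intensities are well separated across the three classes,
#' giving a fixture regime in which detection and classification are
#' learnable by a classical pipeline.
#'
#' @return Named list of per-class morphology parameter lists.
#' @export
default_morphology <- function() {
  list(
    yin = list(radius_mean = 9, radius_sd = 1.2, intensity_mean = 150,
               intensity_sd = 12, irregularity = 0.05, ncr = 0.25),
    `yin-yang` = list(radius_mean = 13, radius_sd = 1.5, intensity_mean = 100,
                      intensity_sd = 12, irregularity = 0.15, ncr = 0.45),
    yang = list(radius_mean = 18, radius_sd = 2.0, intensity_mean = 60,
                intensity_sd = 12, irregularity = 0.40, ncr = 0.70))
}

# analytic IoU of two discs at center distance d
disc_iou <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    inter <- pi * min(r1, r2)^2
  } else {
    a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
    a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
    a3 <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)))
    inter <- a1 + a2 - a3
  }
  inter / (pi * r1^2 + pi * r2^2 - inter)
}

# star-shaped nucleus outline: radial Fourier perturbation of an ellipse
sample_nucleus_shape <- function(radius, irregularity, n_vertices = 28L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  aspect <- exp(runif(1, 0, 0.25) * irregularity * 2 + runif(1, 0, 0.1))
  phi <- runif(1, 0, pi)
  pert <- rep(1, n_vertices)
  for (k in 2:5) {
    ak <- rnorm(1, 0, 0.22) * irregularity
    bk <- rnorm(1, 0, 0.22) * irregularity
    pert <- pert + ak * cos(k * theta) + bk * sin(k * theta)
  }
  pert <- pmax(pert, 0.35)
  a <- radius * sqrt(aspect); b <- radius / sqrt(aspect)
  ex <- a * cos(theta) * pert; ey <- b * sin(theta) * pert
  x <- ex * cos(phi) - ey * sin(phi)
  y <- ex * sin(phi) + ey * cos(phi)
  cbind(x, y)
}

#' Generate one synthetic cytology field
#'
#' Places `n_cells` nuclei (randomly perturbed ellipses on a pale
#' cytoplasm-toned background) by rejection sampling until all pairwise
#' bounding-disc IoUs are at most `overlap_fraction`, then rasterizes the
#' scene as an 8-bit-quantized RGB array. The same spec (same seed) always
#' yields bit-identical output.
#'
#' @param spec A [scene_spec()].
#' @param render If `FALSE`, skip raster painting and return annotations
#'   only (fast path for large statistical sweeps and counts-only cohorts).
#' @param image_id Identifier recorded in the label set.
#' @return List with `image` (`h x w x 3` array in `[0,1]`, or `NULL` when
#'   `render = FALSE`) and `labels` (a [label_set()]).
#' @export
generate_field <- function(spec, render = TRUE, image_id = sprintf("field_%06d", spec$seed)) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    w <- spec$field_size[1]; h <- spec$field_size[2]
    n <- spec$n_cells
    cls <- sample(.CLASSES, n, replace = TRUE, prob = spec$class_mix)
    shapes <- vector("list", n)
    centers <- matrix(0, n, 2)
    radii <- numeric(n)
    max_tries <- 300L * max(n, 1L)
    tries <- 0L
    for (i in seq_len(n)) {
      m <- spec$morphology[[cls[i]]]
      repeat {
        tries <- tries + 1L
        if (tries > max_tries)
          stop(sprintf(paste0("packing failure: could not place %d nuclei of the ",
                              "requested radii in a %dx%d field"), n, w, h))
        r <- max(2, rnorm(1, m$radius_mean, m$radius_sd))
        sh <- sample_nucleus_shape(r, m$irregularity)
        rb <- max(sqrt(rowSums(sh^2)))
        if (2 * rb + 2 >= min(w, h)) next
        cx <- runif(1, rb + 1, w - rb - 1)
        cy <- runif(1, rb + 1, h - rb - 1)
        ok <- TRUE
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            d <- sqrt((cx - centers[j, 1])^2 + (cy - centers[j, 2])^2)
            if (disc_iou(rb, radii[j], d) > spec$overlap_fraction) { ok <- FALSE; break }
          }
        }
        if (ok) {
          shapes[[i]] <- sh; centers[i, ] <- c(cx, cy); radii[i] <- rb
          break
        }
      }
    }
    anns <- lapply(seq_len(n), function(i) {
      poly <- cbind(shapes[[i]][, 1] + centers[i, 1],
                    shapes[[i]][, 2] + centers[i, 2])
      nucleus_annotation(poly, cls[i], validate = FALSE)
    })
    labels <- label_set(image_id, h, w, anns)
    img <- if (render) render_field(labels, spec, centers, radii) else NULL
    list(image = img, labels = labels)
  })
}

# paint background + cytoplasm halos + stained nuclei; quantized to 8 bits
render_field <- function(labels, spec, centers, radii) {
  w <- labels$width; h <- labels$height
  base <- c(0.93, 0.90, 0.94)
  img <- array(0, c(h, w, 3))
  noise <- matrix(rnorm(h * w, 0, 0.012), h, w)
  for (ch in 1:3) img[, , ch] <- base[ch] + noise
  cyto <- c(0.88, 0.82, 0.90)
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  n <- length(labels$annotations)
  for (i in seq_len(n)) {
    a <- labels$annotations[[i]]
    m <- spec$morphology[[a$cls]]
    rc <- radii[i] / sqrt(m$ncr)
    x0 <- max(1L, floor(centers[i, 1] - rc)); x1 <- min(w, ceiling(centers[i, 1] + rc))
    y0 <- max(1L, floor(centers[i, 2] - rc)); y1 <- min(h, ceiling(centers[i, 2] + rc))
    sel <- (xs[y0:y1, x0:x1] - centers[i, 1])^2 + (ys[y0:y1, x0:x1] - centers[i, 2])^2 <= rc^2
    for (ch in 1:3) {
      sub <- img[y0:y1, x0:x1, ch]
      sub[sel] <- 0.6 * sub[sel] + 0.4 * cyto[ch]
      img[y0:y1, x0:x1, ch] <- sub
    }
  }
  tint <- c(0.80, 0.55, 0.95)   # haematoxylin-like purple weighting
  for (i in seq_len(n)) {
    a <- labels$annotations[[i]]
    m <- spec$morphology[[a$cls]]
    intensity <- min(255, max(0, rnorm(1, m$intensity_mean, m$intensity_sd)))
    g <- intensity / 255
    sm <- polygon_submask(a$polygon, h, w)
    if (!any(sm$mask)) next
    idx <- which(sm$mask, arr.ind = TRUE)
    rows <- idx[, 1] + sm$y0; cols <- idx[, 2] + sm$x0
    px_noise <- rnorm(nrow(idx), 0, 0.015)
    for (ch in 1:3) {
      img[cbind(rows, cols, ch)] <- pmin(1, pmax(0, g * tint[ch] + px_noise))
    }
  }
  img[] <- pmin(1, pmax(0, img))   # [] keeps array dims
  img[] <- round(img * 255) / 255
  img
}

#' Generate a seeded set of training fields
#'
#' Convenience wrapper producing `n_fields` independent fields whose
#' per-field seeds derive from `seed`.
#'
#' @param n_fields Number of fields.
#' @param spec Template [scene_spec()]; its `seed` is overridden per field.
#' @param seed Root seed.
#' @param render Rasterize images (see [generate_field()]).
#' @return List of `list(image, labels)` elements.
#' @export
generate_training_set <- function(n_fields, spec = scene_spec(), seed = 1L,
                                  render = TRUE) {
  lapply(seq_len(n_fields), function(i) {
    fs <- spec
    fs$seed <- derive_seed(seed, "field", i)
    generate_field(fs, render = render, image_id = sprintf("field_%04d", i))
  })
}

#' Cohort specification for synthetic patients
#'
#' Encodes the screening-cohort design: a fixed number of patients with a
#' given positive prevalence, several single-field images per patient, and a
#' strongly unbalanced abnormal-cell rate for positive patients (default
#' 1:100, the dense end of the 1:100-1:1000 regime typical of cytology).
#' Negative patients carry no yang cells at all.
#'
#' @param n_patients Number of patients.
#' @param prevalence Fraction of positive patients; exactly
#'   `round(prevalence * n_patients)` are positive.
#' @param fields_per_patient Fields imaged per patient.
#' @param cells_per_field Cells per field.
#' @param abnormal_cell_rate Per-cell probability of yang class in positive
#'   patients.
#' @param yinyang_rate_pos,yinyang_rate_neg Yin-yang (suspected-cell) rates
#'   for positive and negative patients. Equal by default, so that under the
#'   default design the outcome is driven by the yang signal alone and
#'   yin-yang counts are class-independent background.
#' @param age_mean,age_sd Gaussian age distribution (years), truncated to
#'   18-90.
#' @param label_noise Probability that a patient's recorded clinical label
#'   is flipped relative to the generative truth (emulates diagnostic
#'   error).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 400L, prevalence = 211 / 400,
                        fields_per_patient = 3L, cells_per_field = 200L,
                        abnormal_cell_rate = 0.01,
                        yinyang_rate_pos = 0.01, yinyang_rate_neg = 0.01,
                        age_mean = 45, age_sd = 12, label_noise = 0,
                        seed = 1L) {
  if (prevalence < 0 || prevalence > 1) stop("prevalence must lie in [0, 1]")
  if (abnormal_cell_rate <= 0) stop("positive patients need abnormal_cell_rate > 0")
  if (label_noise < 0 || label_noise > 0.5) stop("label_noise must lie in [0, 0.5]")
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 fields_per_patient = as.integer(fields_per_patient),
                 cells_per_field = as.integer(cells_per_field),
                 abnormal_cell_rate = abnormal_cell_rate,
                 yinyang_rate_pos = yinyang_rate_pos,
                 yinyang_rate_neg = yinyang_rate_neg,
                 age_mean = age_mean, age_sd = age_sd,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-field class counts for every patient. With
#' `detail = "counts"` (default) only the count table is produced, which is
#' all the patient-level stage needs; `detail = "annotations"` additionally
#' generates polygon label sets per field via [generate_field()] (using
#' `scene` as the morphology template).
#'
#' @param spec A [cohort_spec()].
#' @param detail `"counts"` or `"annotations"`.
#' @param scene Template [scene_spec()] used when `detail = "annotations"`.
#' @return List with `patients` (data.frame: patient_id, age, label,
#'   true_label), `fields` (data.frame: patient_id, field_id, yin,
#'   yin_yang, yang) and, for `detail = "annotations"`, `label_sets`.
#' @export
generate_cohort <- function(spec, detail = c("counts", "annotations"),
                            scene = scene_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  detail <- match.arg(detail)
  with_seed(spec$seed, {
    n <- spec$n_patients
    n_pos <- round(spec$prevalence * n)
    status <- sample(rep(c("positive", "normal"), c(n_pos, n - n_pos)))
    ages <- round(pmin(90, pmax(18, rnorm(n, spec$age_mean, spec$age_sd))))
    mix_for <- function(st) {
      if (st == "positive")
        c(1 - spec$abnormal_cell_rate - spec$yinyang_rate_pos,
          spec$yinyang_rate_pos, spec$abnormal_cell_rate)
      else c(1 - spec$yinyang_rate_neg, spec$yinyang_rate_neg, 0)
    }
    rows <- vector("list", n * spec$fields_per_patient)
    k <- 0L
    for (i in seq_len(n)) {
      pm <- mix_for(status[i])
      for (f in seq_len(spec$fields_per_patient)) {
        cnt <- as.integer(rmultinom(1, spec$cells_per_field, pm))
        k <- k + 1L
        rows[[k]] <- data.frame(patient_id = sprintf("P%04d", i),
                                field_id = sprintf("P%04d_F%03d", i, f),
                                yin = cnt[1], yin_yang = cnt[2], yang = cnt[3])
      }
    }
    fields <- do.call(rbind, rows)
    observed <- status
    if (spec$label_noise > 0) {
      flip <- runif(n) < spec$label_noise
      observed[flip] <- ifelse(status[flip] == "positive", "normal", "positive")
    }
    patients <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                           age = ages, label = observed, true_label = status,
                           stringsAsFactors = FALSE)
    out <- list(patients = patients, fields = fields, spec = spec)
    if (detail == "annotations") {
      out$label_sets <- lapply(seq_len(nrow(fields)), function(j) {
        pid <- match(fields$patient_id[j], patients$patient_id)
        st <- status[pid]
        fs <- scene
        fs$n_cells <- fields$yin[j] + fields$yin_yang[j] + fields$yang[j]
        fs$class_mix <- stats::setNames(mix_for(st), .CLASSES)
        fs$seed <- derive_seed(spec$seed, "cohort_field", j)
        # force exact drawn counts by rejection-free direct assignment:
        fl <- generate_field(fs, render = FALSE, image_id = fields$field_id[j])
        fl$labels
      })
      # keep the count table consistent with the drawn annotations
      cnts <- t(vapply(out$label_sets, class_counts, integer(3)))
      fields$yin <- cnts[, 1]; fields$yin_yang <- cnts[, 2]; fields$yang <- cnts[, 3]
      out$fields <- fields
    }
    out
  })
}

#' Simulated-pathologist oracle specification
#'
#' @param revision_fidelity Probability that an erroneous pre-label (wrong
#'   class or spurious detection) is corrected to truth.
#' @param miss_add_rate Probability that a missed nucleus is drawn in.
#' @param cost_draw Cost units charged per polygon drawn from scratch.
#' @param cost_fix Cost units charged per corrected label or removed
#'   spurious contour.
#' @param seed Integer seed for the oracle's Bernoulli draws.
#' @return Object of class `oracle_spec`.
#' @export
oracle_spec <- function(revision_fidelity = 1, miss_add_rate = 1,
                        cost_draw = 5, cost_fix = 1, seed = 1L) {
  if (revision_fidelity < 0 || revision_fidelity > 1)
    stop("revision_fidelity must lie in [0, 1]")
  if (miss_add_rate < 0 || miss_add_rate > 1)
    stop("miss_add_rate must lie in [0, 1]")
  if (cost_draw < 0 || cost_fix < 0) stop("costs must be nonnegative")
  structure(list(revision_fidelity = revision_fidelity,
                 miss_add_rate = miss_add_rate,
                 cost_draw = cost_draw, cost_fix = cost_fix,
                 seed = as.integer(seed)),
            class = "oracle_spec")
}

#' Simulate pathologist revision of model pre-labels
#'
#' Matches pre-label detections to ground truth (greedy, IoU >= 0.5 in
#' descending score order) and then emulates a reviewing pathologist:
#' a matched pre-label with the correct class is accepted (snapped to the
#' truth contour) at zero cost; one with a wrong class is corrected to truth
#' with probability `revision_fidelity` (one `cost_fix`); a missed nucleus
#' is drawn in with probability `miss_add_rate` (one `cost_draw`); a
#' spurious pre-label is deleted with probability `revision_fidelity` (one
#' `cost_fix`). With fidelity and miss-add rate both 1 the revised set
#' equals ground truth exactly.
#'
#' @param truth Ground-truth [label_set()].
#' @param prelabels List of detections (see [detect()]) for the same image.
#' @param spec An [oracle_spec()].
#' @param .seed Optional override seed (used by protocol loops to give each
#'   image its own derived stream).
#' @return List with `revised` (a [label_set()]) and `cost` (a ledger:
#'   n_draw, n_fix_label, n_fix_spurious, cost_draw, cost_fix, total).
#' @export
simulate_revision <- function(truth, prelabels, spec, .seed = NULL) {
  stopifnot(inherits(truth, "label_set"), inherits(spec, "oracle_spec"))
  for (d in prelabels)
    if (!identical(d$image_id, truth$image_id))
      stop("simulate_revision: prelabels refer to a different image than truth")
  seed <- if (is.null(.seed)) spec$seed else .seed
  with_seed(seed, {
    m <- match_detections(truth, prelabels, iou_threshold = 0.5)
    anns <- list()
    n_fix_label <- 0L; n_draw <- 0L; n_fix_spurious <- 0L
    for (ti in seq_along(truth$annotations)) {
      a <- truth$annotations[[ti]]
      di <- m$assignment$detection[m$assignment$truth == ti]
      if (length(di) == 1L && !is.na(di)) {
        pred_cls <- prelabels[[di]]$cls
        if (identical(pred_cls, a$cls)) {
          anns[[length(anns) + 1L]] <- a
        } else if (runif(1) < spec$revision_fidelity) {
          n_fix_label <- n_fix_label + 1L
          anns[[length(anns) + 1L]] <- a
        } else {
          anns[[length(anns) + 1L]] <-
            nucleus_annotation(a$polygon, pred_cls, validate = FALSE)
        }
      } else {
        if (runif(1) < spec$miss_add_rate) {
          n_draw <- n_draw + 1L
          anns[[length(anns) + 1L]] <- a
        }
      }
    }
    matched_det <- m$assignment$detection[!is.na(m$assignment$detection)]
    for (di in setdiff(seq_along(prelabels), matched_det)) {
      if (runif(1) < spec$revision_fidelity) {
        n_fix_spurious <- n_fix_spurious + 1L
      } else {
        d <- prelabels[[di]]
        anns[[length(anns) + 1L]] <-
          nucleus_annotation(d$polygon, d$cls, validate = FALSE)
      }
    }
    cost <- list(n_draw = n_draw, n_fix_label = n_fix_label,
                 n_fix_spurious = n_fix_spurious,
                 cost_draw = spec$cost_draw, cost_fix = spec$cost_fix,
                 total = n_draw * spec$cost_draw +
                   (n_fix_label + n_fix_spurious) * spec$cost_fix)
    list(revised = label_set(truth$image_id, truth$height, truth$width, anns),
         cost = cost)
  })
}

#' Write a field image as PNG
#'
#' @param image `h x w x 3` array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}
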