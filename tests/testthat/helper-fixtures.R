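# Shared fixtures, built once per test run and cached.

.fx <- new.env()

fixture_train_fields <- function() {
  if (is.null(.fx$train))
    .fx$train <- generate_training_set(30, scene_spec(n_cells = 30), seed = 11)
  .fx$train
}

fixture_test_fields <- function() {
  if (is.null(.fx$test))
    .fx$test <- generate_training_set(10, scene_spec(n_cells = 30), seed = 99)
  .fx$test
}

fixture_detector <- function() {
  if (is.null(.fx$detector))
    .fx$detector <- train_detector(fixture_train_fields(), seed = 5)
  .fx$detector
}

fixture_noisy_cohort <- function() {
  if (is.null(.fx$cohort))
    .fx$cohort <- generate_cohort(cohort_spec(label_noise = 0.02, seed = 42))
  .fx$cohort
}

# independent per-pixel even-odd point-in-polygon rasterizer (oracle)
brute_polygon_mask <- function(poly, h, w) {
  m <- matrix(FALSE, h, w)
  n <- nrow(poly)
  for (r in seq_len(h)) {
    py <- r - 0.5
    for (cc in seq_len(w)) {
      px <- cc - 0.5
      cross <- 0L
      for (i in seq_len(n)) {
        j <- i %% n + 1L
        y1 <- poly[i, 2]; y2 <- poly[j, 2]
        if ((y1 > py) != (y2 > py)) {
          xint <- poly[i, 1] + (py - y1) * (poly[j, 1] - poly[i, 1]) / (y2 - y1)
          if (px < xint) cross <- cross + 1L
        }
      }
      m[r, cc] <- (cross %% 2L) == 1L
    }
  }
  m
}

# star-shaped random test polygon centred in an h x w frame
random_star_polygon <- function(h, w, n_vertices = 12) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 0.15, 0.45) * min(h, w)
  cbind(w / 2 + rad * cos(th), h / 2 + rad * sin(th))
}

# brute-force rectangle-rule PR-AUC over every unique threshold (oracle)
brute_pr_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  r_prev <- 0; auc <- 0
  for (t in thr) {
    sel <- scores >= t
    p <- sum(labels[sel]) / sum(sel)
    r <- sum(labels[sel]) / sum(labels)
    auc <- auc + (r - r_prev) * p
    r_prev <- r
  }
  auc
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
enumerate_signed_rank_p <- function(x, y) {
  d <- (x - y)[x != y]
  r <- rank(abs(d))
  n <- length(d)
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(w_all <= obs + 1e-9), mean(w_all >= obs - 1e-9)))
}

# detections that copy ground-truth polygons (optionally perturbed class)
detections_from_truth <- function(labels, scores = NULL, classes = NULL) {
  n <- length(labels$annotations)
  if (is.null(scores)) scores <- rep(0.9, n)
  lapply(seq_len(n), function(i) {
    a <- labels$annotations[[i]]
    list(image_id = labels$image_id, polygon = a$polygon,
         cls = if (is.null(classes)) a$cls else classes[i],
         score = scores[i])
  })
}
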