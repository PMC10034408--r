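test_that("smooth-L1 matches its closed form and is continuous at the knee", {
  expect_identical(smooth_l1(0), 0)
  expect_identical(smooth_l1(0.5), 0.125)
  expect_identical(smooth_l1(-2), 1.5)
  expect_equal(smooth_l1(1 - 1e-9), smooth_l1(1 + 1e-9), tolerance = 1e-6)
  expect_true(all(smooth_l1(seq(-5, 5, by = 0.1)) >= 0))
})

test_that("weighted cross-entropy: zero at certainty, linear in the true-class weight", {
  expect_identical(classification_loss(c(1, 0, 0), c(1, 0, 0)), 0)
  l1 <- classification_loss(c(0.5, 0.3, 0.2), c(1, 0, 0), c(1, 1, 1))
  expect_equal(l1, -log(0.5), tolerance = 1e-12)
  l2 <- classification_loss(c(0.5, 0.3, 0.2), c(1, 0, 0), c(2, 1, 1))
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  # invariant to permuting the non-true classes when their weights are equal
  la <- classification_loss(c(0.6, 0.3, 0.1), c(1, 0, 0), c(1.5, 2, 2))
  lb <- classification_loss(c(0.6, 0.1, 0.3), c(1, 0, 0), c(1.5, 2, 2))
  expect_identical(la, lb)
  expect_error(classification_loss(c(0.6, 0.6), c(1, 0)), "sum to 1")
  expect_error(classification_loss(c(0.5, 0.5), c(1, 1)), "one-hot")
  expect_warning(classification_loss(c(0, 1), c(1, 0)), "clamped")
})

test_that("RPN loss gates regression on positive anchors and matches hand arithmetic", {
  t0 <- rbind(c(0.5, 0, 0, 0), c(9, 9, 9, 9))
  tstar <- rbind(rep(0, 4), rep(0, 4))
  r <- rpn_loss(p = c(0.9, 0.2), p_star = c(1, 0), t = t0, t_star = tstar)
  expect_equal(r$cls_term, (-log(0.9) - log(0.8)) / 2, tolerance = 1e-12)
  expect_equal(r$reg_term, smooth_l1(0.5), tolerance = 1e-12)  # only anchor 1
  expect_equal(r$total, r$cls_term + r$reg_term)

  # all-negative anchors: regression term exactly 0 regardless of t
  r0 <- rpn_loss(p = c(0.1, 0.2), p_star = c(0, 0), t = t0 + 100, t_star = tstar)
  expect_identical(r0$reg_term, 0)

  # perturbing t of negative anchors never changes the loss
  ra <- rpn_loss(p = c(0.7, 0.3), p_star = c(1, 0), t = t0, t_star = tstar)
  t_pert <- t0; t_pert[2, ] <- t_pert[2, ] + rnorm(4, 0, 50)
  rb <- rpn_loss(p = c(0.7, 0.3), p_star = c(1, 0), t = t_pert, t_star = tstar)
  expect_identical(ra$total, rb$total)

  # exact box prediction for the single positive anchor: zero regression
  rp <- rpn_loss(p = 0.8, p_star = 1, t = rbind(c(1, 2, 3, 4)),
                 t_star = rbind(c(1, 2, 3, 4)))
  expect_identical(rp$reg_term, 0)
  expect_error(rpn_loss(p = 0.5, p_star = 1, t = rbind(rep(0, 4)),
                        t_star = rbind(rep(0, 4)), n_cls = 0), "positive")
})

test_that("total loss sums branches; mask BCE has its closed-form anchors", {
  expect_identical(total_loss(1.0, 2.0, 0.5), 3.5)
  truth <- matrix(c(0, 1, 1, 0), 2)
  expect_identical(mask_bce(truth, truth) < 1e-10, TRUE)
  expect_equal(mask_bce(matrix(0.5, 2, 2), truth), log(2), tolerance = 1e-12)
})

test_that("inverse-frequency class weights normalize, cap and reject zeros", {
  expect_identical(compute_class_weights(c(100, 100, 100)), c(1, 1, 1))
  expect_identical(compute_class_weights(c(1000, 10, 10)), c(1, 100, 100))
  expect_identical(compute_class_weights(c(1000, 10, 10), cap = 50), c(1, 50, 50))
  expect_error(compute_class_weights(c(100, 0, 10)), "oversample")
})

test_that("positive-image oversampling reaches the target ratio and keeps originals", {
  mk <- function(cls) {
    poly <- rbind(c(2, 2), c(8, 2), c(5, 8))
    list(image = NULL,
         labels = label_set(paste0("i", sample.int(1e6, 1)), 16, 16,
                            list(nucleus_annotation(poly, cls))))
  }
  set.seed(1)
  fields <- c(list(mk("yang")), replicate(9, mk("yin"), simplify = FALSE))
  out <- oversample_positives(fields, target_ratio = 0.5)
  expect_length(out, 18L)
  is_pos <- vapply(out, function(f) any(class_counts(f$labels)[c(2, 3)] > 0), TRUE)
  expect_identical(sum(is_pos), 9L)
  expect_identical(out[seq_along(fields)], fields)
  expect_identical(oversample_positives(fields, target_ratio = 0.05), fields)
  expect_identical(oversample_positives(fields, 0.5),
                   oversample_positives(fields, 0.5))
  expect_error(oversample_positives(replicate(3, mk("yin"), simplify = FALSE), 0.5),
               "no images contain abnormal cells")
})

test_that("reference detector learns the separable fixture (mAP and class accuracy)", {
  model <- fixture_detector()
  ev <- evaluate_detector(model, fixture_test_fields())
  expect_gte(ev$map, 0.8)
  cm <- ev$confusion
  expect_gte(sum(diag(cm[, 1:3])) / sum(cm), 0.95)
})

test_that("detector training and prediction are deterministic under a fixed seed", {
  m1 <- fixture_detector()
  m2 <- train_detector(fixture_train_fields(), seed = 5)
  probe <- fixture_test_fields()[[1]]
  d1 <- detect(m1, probe$image, "probe")
  d2 <- detect(m2, probe$image, "probe")
  expect_identical(d1, d2)
})

test_that("detections satisfy the NMS contract and blank fields yield nothing", {
  model <- fixture_detector()
  probe <- fixture_test_fields()[[2]]
  dets <- detect(model, probe$image, "probe")
  expect_gt(length(dets), 0L)
  if (length(dets) > 1L) {
    for (i in seq_along(dets)[-1]) for (j in seq_len(i - 1)) {
      expect_lte(polygon_iou(dets[[i]]$polygon, dets[[j]]$polygon,
                             probe$labels$height, probe$labels$width), 0.5)
    }
  }
  for (d in dets) {
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    expect_equal(d$score, max(d$prob))
  }
  blank <- array(rep(c(0.93, 0.90, 0.94), each = 128 * 128), c(128, 128, 3))
  expect_length(detect(model, blank, "blank"), 0L)
})

test_that("a lone large dark irregular nucleus is detected and called yang", {
  model <- fixture_detector()
  f <- generate_field(scene_spec(n_cells = 1, class_mix = c(0, 0, 1), seed = 55))
  dets <- detect(model, f$image, "one_yang")
  expect_length(dets, 1L)
  expect_identical(dets[[1]]$cls, "yang")
})

test_that("degenerate single-class training warns and predicts that class", {
  fields <- generate_training_set(6, scene_spec(n_cells = 15,
                                                class_mix = c(1, 0, 0)),
                                  seed = 61)
  expect_warning(model <- train_detector(fields, seed = 2), "only class")
  dets <- detect(model, fields[[1]]$image, "x")
  expect_true(all(vapply(dets, `[[`, "", "cls") == "yin"))
})

test_that("save/load reproduces predictions bit-identically", {
  model <- fixture_detector()
  path <- withr::local_tempfile(fileext = ".rds")
  save_detector(model, path)
  restored <- load_detector(path)
  probe <- fixture_test_fields()[[3]]
  expect_identical(detect(model, probe$image, "p"), detect(restored, probe$image, "p"))
  expect_identical(restored$config_digest, model$config_digest)
  expect_error(detect(structure(list(trained = FALSE), class = "cyto_detector"),
                      probe$image), "not a trained")
})
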