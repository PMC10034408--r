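# verbatim printed confusion matrices used as metric inputs
TABLE_T1 <- rbind(c(2839, 36, 17, 23), c(0, 27, 15, 1), c(1, 4, 100, 3))
TABLE_A3 <- rbind(c(2851, 44, 18, 2), c(0, 28, 15, 0), c(1, 0, 106, 0))

test_that("matching perfect predictions gives a diagonal matrix; none gives all-missing", {
  f <- generate_field(scene_spec(seed = 33, n_cells = 15), render = FALSE)
  perfect <- detections_from_truth(f$labels)
  m <- match_detections(f$labels, perfect)
  expect_identical(sum(m$confusion[, "missing"]), 0L)
  expect_identical(m$spurious, 0L)
  expect_identical(sum(diag(m$confusion[, 1:3])), 15L)
  expect_identical(as.integer(rowSums(m$confusion)),
                   unname(class_counts(f$labels)))

  m0 <- match_detections(f$labels, list())
  expect_identical(unname(m0$confusion[, "missing"]), unname(class_counts(f$labels)))
  expect_error(match_detections(f$labels, perfect, iou_threshold = 0), "0, 1")
})

test_that("greedy matching prefers the higher-score candidate; loser is spurious", {
  sq <- rbind(c(4, 4), c(14, 4), c(14, 14), c(4, 14))
  truth <- label_set("t", 32, 32, list(nucleus_annotation(sq, "yang")))
  two <- list(
    list(image_id = "t", polygon = sq, cls = "yang", score = 0.6),
    list(image_id = "t", polygon = sq + 0.5, cls = "yin", score = 0.9))
  m <- match_detections(truth, two)
  expect_identical(m$assignment$detection, 2L)   # higher score wins
  expect_identical(m$spurious, 1L)
  expect_identical(unname(m$confusion["yang", "yin"]), 1L)

  # 3-cell toy against exhaustive one-to-one assignment enumeration
  t3 <- label_set("t3", 48, 48, list(
    nucleus_annotation(sq, "yin"),
    nucleus_annotation(sq + 16, "yang"),
    nucleus_annotation(sq + c(16, 0), "yin-yang")))
  d3 <- detections_from_truth(t3, scores = c(0.5, 0.95, 0.7))
  m3 <- match_detections(t3, d3)
  # each detection copies one truth polygon exactly (IoU 1 with it, and
  # below threshold elsewhere): the only feasible assignment is identity
  feasible <- lapply(1:3, function(ti)
    which(vapply(1:3, function(di)
      polygon_iou(t3$annotations[[ti]]$polygon, d3[[di]]$polygon, 48, 48) >= 0.5,
      TRUE)))
  expect_identical(unname(unlist(feasible)), 1:3)
  expect_identical(m3$assignment$detection, 1:3)
})

test_that("binary metrics reproduce the published per-class and composite values", {
  a3y <- binary_metrics(TABLE_A3, "yin", percent = TRUE)
  expect_equal(round(a3y$sensitivity, 2), 97.80)
  expect_equal(round(a3y$accuracy, 2), 97.88)
  a3c <- binary_metrics(TABLE_A3, c("yin-yang", "yang"), percent = TRUE)
  expect_equal(round(a3c$sensitivity, 2), 99.33)
  expect_equal(round(a3c$specificity, 2), 97.87)
  expect_equal(round(a3c$accuracy, 2), 97.94)
  t1y <- binary_metrics(TABLE_T1, "yin", percent = TRUE)
  expect_equal(round(t1y$sensitivity, 2), 97.39)
  expect_equal(round(t1y$accuracy, 2), 97.49)
  t1c <- binary_metrics(TABLE_T1, c("yin-yang", "yang"), percent = TRUE)
  expect_equal(round(t1c$sensitivity, 2), 96.69)
  expect_equal(round(t1c$specificity, 2), 98.18)
  expect_equal(round(t1c$accuracy, 2), 98.11)
})

test_that("binary metrics: perfect diagonal gives 100%, degenerate tallies flag", {
  diag3 <- cbind(diag(c(5L, 6L, 7L)), rep(0L, 3))
  m <- binary_metrics(diag3, c("yin-yang", "yang"), percent = TRUE)
  for (v in c("sensitivity", "specificity", "accuracy", "ppv", "npv"))
    expect_equal(m[[v]], 100)
  empty_pos <- rbind(c(10, 0, 0, 0), rep(0L, 4), rep(0L, 4))
  m2 <- binary_metrics(empty_pos, c("yin-yang", "yang"))
  expect_true("sensitivity" %in% m2$undefined)
  expect_true(is.na(m2$sensitivity))
  expect_error(binary_metrics(TABLE_A3, character(0)), "nonempty")
})

test_that("confusion conservation: row sums equal truth counts; tallies partition cells", {
  set.seed(5150)
  for (k in 1:25) {
    cm <- matrix(rpois(12, 20), 3, 4)
    truth_counts <- rowSums(cm)
    for (pos in list("yin", "yang", c("yin-yang", "yang"), c("yin", "yang"))) {
      bm <- binary_metrics(cm, pos)
      expect_identical(sum(bm$tally), sum(cm))
      for (v in c("sensitivity", "specificity", "accuracy", "ppv", "npv")) {
        if (!v %in% bm$undefined) {
          expect_gte(bm[[v]], 0); expect_lte(bm[[v]], 1)
        }
      }
    }
    expect_equal(unname(rowSums(confusion_matrix3m(cm))),
                 as.numeric(truth_counts))
  }
})

test_that("F1 and G-mean follow their formulas including boundary cases", {
  r <- f1_gmean(1, 1, 1)
  expect_identical(r$f1, 1); expect_identical(r$gmean, 1)
  expect_identical(f1_gmean(1, 0, 1)$f1, 0)
  expect_equal(f1_gmean(0.5, 0.9, 0.4)$gmean, 0.6, tolerance = 1e-12)
  z <- f1_gmean(0, 0, 0.5)
  expect_identical(z$f1, 0)
  expect_identical(z$flag, "f1_defined_as_zero")
})

test_that("PR-AUC: perfect separation gives 1; null scores track prevalence", {
  expect_identical(pr_curve_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1)
  set.seed(88)
  labels <- rbinom(1000, 1, 0.3)
  scores <- runif(1000)
  auc <- pr_curve_auc(scores, labels)$auc
  expect_lt(abs(auc - mean(labels)), 0.05)
  expect_error(pr_curve_auc(runif(5), rep(0, 5)), "at least one positive")
})

test_that("PR curve recall is monotone and all points lie in the unit square", {
  set.seed(12)
  for (k in 1:10) {
    n <- sample(5:50, 1)
    labels <- rbinom(n, 1, 0.4); if (sum(labels) == 0) labels[1] <- 1
    cv <- pr_curve_auc(round(runif(n), 2), labels)$curve
    expect_true(all(diff(cv$recall) >= 0))
    expect_true(all(cv$recall >= 0 & cv$recall <= 1))
    expect_true(all(cv$precision >= 0 & cv$precision <= 1))
  }
})

test_that("mAP/mAR: perfect, half-missed and hand-computed toy cases", {
  f <- generate_field(scene_spec(seed = 44, n_cells = 12,
                                 class_mix = c(0.5, 0, 0.5)), render = FALSE)
  perfect <- detections_from_truth(f$labels)
  mm <- suppressWarnings(map_mar(list(f$labels), list(perfect)))
  expect_equal(mm$map, 1); expect_equal(mm$mar, 1)

  # drop every yang detection: that class scores AP 0, the other stays 1
  only_yin <- Filter(function(d) d$cls == "yin", perfect)
  counts <- class_counts(f$labels)
  if (counts[["yin"]] > 0 && counts[["yang"]] > 0) {
    mm2 <- suppressWarnings(map_mar(list(f$labels), list(only_yin)))
    expect_equal(mm2$map, 0.5)
  }

  # hand-built scored list: AP by explicit rectangle arithmetic
  ap <- average_precision(scores = c(0.9, 0.8, 0.7, 0.6),
                          correct = c(TRUE, FALSE, TRUE, FALSE), n_truth = 2)
  expect_equal(ap$ap, 0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_equal(ap$final_recall, 1)
})

test_that("Friedman: strict dominance closed form, tied table, brute-force agreement", {
  strict <- rbind(a = 11:20, b = 1:10, c = -9:0)
  fr <- friedman_compare(strict)
  expect_equal(unname(fr$mean_ranks), c(1, 2, 3))
  expect_equal(fr$statistic, 20, tolerance = 1e-9)  # 12n/(k(k+1)) * sum dev^2
  expect_lt(fr$p_value, 0.01)

  expect_warning(tied <- friedman_compare(matrix(1, 3, 4)), "tied")
  expect_identical(tied$statistic, 0)
  expect_identical(tied$p_value, 1)

  set.seed(303)
  toy <- matrix(sample(100, 12), 3, 4)
  fr2 <- friedman_compare(toy)
  ranks <- apply(toy, 2, rank)
  n <- ncol(toy); k <- nrow(toy)
  brute_stat <- 12 / (n * k * (k + 1)) * sum(rowSums(ranks)^2) - 3 * n * (k + 1)
  expect_equal(fr2$statistic, brute_stat, tolerance = 1e-9)
  expect_error(friedman_compare(toy[1:2, ]), ">= 3 methods")
})

test_that("Wilcoxon signed-rank: exact enumeration oracle, wilcox.test cross-check, Holm", {
  # all-positive differences with tied ranks, n = 10: p = 2/1024
  expect_equal(wilcoxon_signed_rank(11:20, 1:10)$p_value, 2 / 1024,
               tolerance = 1e-12)
  # enumeration oracle over all 2^n sign patterns on random data, n <= 10
  set.seed(71)
  for (k in 1:8) {
    n <- sample(6:10, 1)
    x <- sample(20, n, replace = TRUE); y <- sample(20, n, replace = TRUE)
    if (all(x == y)) x[1] <- x[1] + 1
    expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                 enumerate_signed_rank_p(x, y), tolerance = 1e-9)
  }
  # untied case agrees with the reference implementation's exact test
  set.seed(72)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  expect_identical(wilcoxon_signed_rank(1:5, 1:5)$flag, "all_differences_zero")

  m <- rbind(a = 11:20, b = 1:10, c = rnorm(10))
  pw <- wilcoxon_pairwise(m)
  expect_true(all(pw$p_holm >= pw$p_raw))
  expect_identical(nrow(pw), 3L)
})
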