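# Evaluation machinery: IoU matching into the 3-class-plus-missing
# confusion matrix, binary screening metrics, F1/G-mean, rectangle-rule
# PR-curve AUC, mAP/mAR at a fixed IoU, and Friedman/Wilcoxon model
# comparisons.

#' Match detections to ground truth and tabulate the confusion matrix
#'
#' Greedy one-to-one matching in descending detection score: each detection
#' claims the unmatched ground-truth nucleus of highest IoU at or above the
#' threshold. Matched truth cells contribute to the (truth class, predicted
#' class) cell; unmatched truth cells fall in the `missing` column.
#' Detections matching no truth are tallied separately as spurious and do
#' not enter the 3 x 4 matrix.
#'
#' @param truth A [label_set()].
#' @param detections List of detections for the same image.
#' @param iou_threshold Match threshold in `(0, 1]` (default 0.5).
#' @return List with `assignment` (data.frame truth/detection/iou),
#'   `confusion` (3 x 4 matrix, columns yin, yin-yang, yang, missing) and
#'   `spurious` (count of unmatched detections).
#' @export
match_detections <- function(truth, detections, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must lie in (0, 1]")
  h <- truth$height; w <- truth$width
  nt <- length(truth$annotations)
  nd <- length(detections)
  tmasks <- lapply(truth$annotations, function(a) polygon_submask(a$polygon, h, w))
  dmasks <- lapply(detections, function(d) {
    if (!is.null(d$.submask)) d$.submask else polygon_submask(d$polygon, h, w)
  })
  scores <- if (nd) vapply(detections, `[[`, 0, "score") else numeric(0)
  ord <- order(-scores, seq_len(nd))
  matched_t <- rep(NA_integer_, nt)
  matched_d <- rep(NA_integer_, nd)
  for (di in ord) {
    best <- iou_threshold - 1e-12; best_t <- NA_integer_
    for (ti in seq_len(nt)) {
      if (!is.na(matched_t[ti])) next
      iou <- submask_iou(dmasks[[di]], tmasks[[ti]])
      if (iou >= iou_threshold && iou > best) { best <- iou; best_t <- ti }
    }
    if (!is.na(best_t)) { matched_t[best_t] <- di; matched_d[di] <- best_t }
  }
  cm <- empty_confusion()
  tcls <- label_classes(truth)
  for (ti in seq_len(nt)) {
    if (is.na(matched_t[ti])) {
      cm[tcls[ti], "missing"] <- cm[tcls[ti], "missing"] + 1L
    } else {
      pcls <- detections[[matched_t[ti]]]$cls
      cm[tcls[ti], pcls] <- cm[tcls[ti], pcls] + 1L
    }
  }
  assignment <- data.frame(truth = seq_len(nt), detection = matched_t,
                           row.names = NULL)
  list(assignment = assignment, confusion = cm,
       spurious = sum(is.na(matched_d)))
}

empty_confusion <- function() {
  matrix(0L, 3, 4, dimnames = list(truth = .CLASSES,
                                   predicted = c(.CLASSES, "missing")))
}

#' Confusion matrix from explicit counts
#'
#' Convenience constructor for a 3 x 4 (truth x predicted-plus-missing)
#' cell-classification confusion matrix.
#'
#' @param counts 3 x 4 numeric matrix, rows yin, yin-yang, yang; columns
#'   yin, yin-yang, yang, missing.
#' @return Validated integer matrix with canonical dimnames.
#' @export
confusion_matrix3m <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 4))) stop("confusion matrix must be 3 x 4")
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  dimnames(counts) <- list(truth = .CLASSES, predicted = c(.CLASSES, "missing"))
  storage.mode(counts) <- "integer"
  counts
}

#' Binary screening metrics from the 3 x 4 confusion matrix
#'
#' Collapses the three-class-plus-missing matrix into a binary tally for a
#' chosen positive class set and applies the standard screening formulas
#' (sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy, PPV,
#' NPV). A truth cell of a positive class counts TP when predicted as any
#' positive class and FN when predicted negative *or missed*; a
#' negative-class truth cell counts FP when predicted positive and TN when
#' predicted negative or missed (missing-as-predicted-negative policy).
#'
#' @param cm 3 x 4 matrix from [match_detections()] or
#'   [confusion_matrix3m()].
#' @param positive Character vector of positive classes, e.g. `"yin"` or
#'   `c("yin-yang", "yang")`.
#' @param percent Report metrics on the 0-100 scale (2-decimal style) when
#'   `TRUE`; fractions otherwise.
#' @return List with `tally` (TP/FN/FP/TN), the five metrics, and
#'   `undefined` naming any metric with a zero denominator (reported as
#'   `NA`).
#' @export
binary_metrics <- function(cm, positive, percent = FALSE) {
  cm <- confusion_matrix3m(cm)
  positive <- vapply(positive, normalize_class, "")
  if (length(positive) == 0L) stop("positive class set must be nonempty")
  negative <- setdiff(.CLASSES, positive)
  pos_pred <- positive
  neg_pred <- c(negative, "missing")
  tp <- sum(cm[positive, pos_pred, drop = FALSE])
  fn <- sum(cm[positive, neg_pred, drop = FALSE])
  fp <- sum(cm[negative, pos_pred, drop = FALSE])
  tn <- sum(cm[negative, neg_pred, drop = FALSE])
  res <- list(tally = c(TP = tp, FN = fn, FP = fp, TN = tn))
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  res$sensitivity <- safe(tp, tp + fn)
  res$specificity <- safe(tn, tn + fp)
  res$accuracy <- safe(tp + tn, tp + tn + fp + fn)
  res$ppv <- safe(tp, tp + fp)
  res$npv <- safe(tn, tn + fn)
  metric_names <- c("sensitivity", "specificity", "accuracy", "ppv", "npv")
  res$undefined <- metric_names[vapply(res[metric_names], is.na, TRUE)]
  if (percent) for (m in metric_names) res[[m]] <- 100 * res[[m]]
  res
}

#' F1 score and G-mean
#'
#' `F1 = 2 P R / (P + R)` and `G-mean = sqrt(R x specificity)`. When
#' precision and recall are both zero, F1 is defined as 0 and flagged.
#'
#' @param precision,recall,specificity Values in `[0, 1]`.
#' @return List with `f1`, `gmean` and `flag` (character, possibly empty).
#' @export
f1_gmean <- function(precision, recall, specificity) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1,
            specificity >= 0, specificity <= 1)
  flag <- character(0)
  if (precision + recall == 0) {
    f1 <- 0
    flag <- "f1_defined_as_zero"
  } else f1 <- 2 * precision * recall / (precision + recall)
  list(f1 = f1, gmean = sqrt(recall * specificity), flag = flag)
}

#' Precision-recall curve and rectangle-rule AUC
#'
#' Sweeps the decision threshold over the unique scores in descending
#' order; at each threshold `t` everything scoring at least `t` is called
#' positive. The AUC is the uninterpolated rectangle sum
#' `sum_n (R_n - R_{n-1}) P_n` with `R_0 = 0`.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical), at least one positive.
#' @param n_positive Recall denominator; defaults to `sum(labels)`. Supply
#'   a larger value when scored items cover only part of the positive set
#'   (e.g. detections vs. all ground-truth nuclei).
#' @return List with `curve` (data.frame threshold, recall, precision) and
#'   `auc`.
#' @export
pr_curve_auc <- function(scores, labels, n_positive = NULL) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  if (is.null(n_positive)) n_positive <- sum(labels)
  if (n_positive < 1) stop("PR curve requires at least one positive label")
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(s, fromLast = TRUE)   # final index at each unique score
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  recall <- tp / n_positive
  precision <- tp / (tp + fp)
  auc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = thr, recall = recall,
                          precision = precision),
       auc = auc)
}

#' Average precision for one scored detection list
#'
#' Rectangle-rule area under the precision-recall curve traced as the score
#' threshold descends, with the recall denominator fixed at the number of
#' ground-truth instances.
#'
#' @param scores Detection scores.
#' @param correct Logical: detection matched a ground-truth instance.
#' @param n_truth Number of ground-truth instances (recall denominator).
#' @return List with `ap` and `final_recall` (recall with every detection
#'   accepted).
#' @export
average_precision <- function(scores, correct, n_truth) {
  if (n_truth < 1) stop("average_precision: no ground-truth instances")
  if (length(scores) == 0L) return(list(ap = 0, final_recall = 0))
  pr <- pr_curve_auc(scores, correct, n_positive = n_truth)
  list(ap = pr$auc, final_recall = pr$curve$recall[nrow(pr$curve)])
}

#' Mean average precision and recall over classes at fixed IoU
#'
#' For each class, detections predicted as that class are matched greedily
#' (score-descending, one-to-one) against ground-truth nuclei of the same
#' class at the IoU threshold, per image; the pooled scored match
#' indicators give AP by the rectangle rule and AR as the final-threshold
#' recall. Classes without ground truth are excluded with a warning;
#' spurious detections count as false positives in precision (COCO
#' convention).
#'
#' @param truth_sets List of [label_set()]s.
#' @param detection_sets List (parallel to `truth_sets`) of detection
#'   lists.
#' @param iou_threshold Match threshold (default 0.5).
#' @return List with `per_class` (data.frame class, n_truth, ap, ar),
#'   `map` and `mar` (unweighted class means, in `[0, 1]`).
#' @export
map_mar <- function(truth_sets, detection_sets, iou_threshold = 0.5) {
  stopifnot(length(truth_sets) == length(detection_sets))
  per <- lapply(.CLASSES, function(cl) {
    scores <- numeric(0); correct <- logical(0); n_truth <- 0L
    for (i in seq_along(truth_sets)) {
      tr <- truth_sets[[i]]
      tidx <- which(label_classes(tr) == cl)
      n_truth <- n_truth + length(tidx)
      dets <- Filter(function(d) identical(d$cls, cl), detection_sets[[i]])
      if (length(dets) == 0L) next
      tmasks <- lapply(tidx, function(j)
        polygon_submask(tr$annotations[[j]]$polygon, tr$height, tr$width))
      dmasks <- lapply(dets, function(d) {
        if (!is.null(d$.submask)) d$.submask
        else polygon_submask(d$polygon, tr$height, tr$width)
      })
      ds <- vapply(dets, `[[`, 0, "score")
      ord <- order(-ds, seq_along(ds))
      taken <- rep(FALSE, length(tidx))
      ok <- logical(length(dets))
      for (di in ord) {
        best <- 0; best_t <- NA_integer_
        for (tj in seq_along(tidx)) {
          if (taken[tj]) next
          iou <- submask_iou(dmasks[[di]], tmasks[[tj]])
          if (iou >= iou_threshold && iou > best) { best <- iou; best_t <- tj }
        }
        if (!is.na(best_t)) { taken[best_t] <- TRUE; ok[di] <- TRUE }
      }
      scores <- c(scores, ds); correct <- c(correct, ok)
    }
    list(class = cl, n_truth = n_truth, scores = scores, correct = correct)
  })
  has_truth <- vapply(per, function(p) p$n_truth > 0L, TRUE)
  if (!any(has_truth)) stop("map_mar: no class has ground-truth instances")
  if (!all(has_truth))
    warning(sprintf("classes with no ground truth excluded: %s",
                    paste(vapply(per[!has_truth], `[[`, "", "class"),
                          collapse = ", ")))
  rows <- lapply(per[has_truth], function(p) {
    ap <- average_precision(p$scores, p$correct, p$n_truth)
    data.frame(class = p$class, n_truth = p$n_truth,
               ap = ap$ap, ar = ap$final_recall)
  })
  per_class <- do.call(rbind, rows)
  list(per_class = per_class, map = mean(per_class$ap), mar = mean(per_class$ar))
}

#' Friedman test across methods over folds
#'
#' Ranks the methods within every fold (average ranks on ties) and applies
#' the Friedman chi-square test. Completely tied tables return statistic 0
#' and p = 1 with a warning.
#'
#' @param metric_matrix Numeric methods x folds matrix (higher = better or
#'   worse, direction only affects rank orientation, not the statistic).
#' @return List with `statistic`, `p_value`, `mean_ranks` and `df`.
#' @export
friedman_compare <- function(metric_matrix) {
  m <- as.matrix(metric_matrix)
  if (nrow(m) < 3L) stop("friedman_compare needs >= 3 methods")
  if (ncol(m) < 2L) stop("friedman_compare needs >= 2 folds")
  ranks <- apply(-m, 2, rank)         # within-fold ranks, 1 = best
  mean_ranks <- rowMeans(ranks)
  if (all(abs(mean_ranks - mean(mean_ranks)) < 1e-12) &&
      all(apply(ranks, 2, function(r) length(unique(r)) == 1L))) {
    warning("all methods tied in every fold")
    return(list(statistic = 0, p_value = 1, mean_ranks = mean_ranks,
                df = nrow(m) - 1))
  }
  ft <- stats::friedman.test(t(m))
  stat <- unname(ft$statistic)
  if (!is.finite(stat)) {
    warning("degenerate (fully tied) Friedman table")
    stat <- 0
  }
  list(statistic = stat,
       p_value = if (is.finite(stat) && stat == 0) 1 else unname(ft$p.value),
       mean_ranks = mean_ranks, df = unname(ft$parameter))
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test. Zero differences are dropped; absolute
#' differences are ranked with average ranks on ties. For up to 25
#' effective pairs the p-value is exact, computed over all `2^n` sign
#' patterns via a generating-function convolution (so tied ranks are
#' handled exactly too, unlike the classical exact tables); larger samples
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`
#'   and `flag` (`"all_differences_zero"` when the test is degenerate).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L)
    return(list(statistic = 0, p_value = 1, flag = "all_differences_zero"))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  n <- length(d)
  if (n <= 25L) {
    # exact null distribution of 2*W+ (doubling makes mid-ranks integral)
    r2 <- as.integer(round(2 * r))
    dist <- c(1, rep(0, sum(r2)))        # coefficients over 0..sum(r2)
    for (ri in r2) {
      shifted <- c(rep(0, ri), dist[seq_len(length(dist) - ri)])
      dist <- dist + shifted
    }
    dist <- dist / sum(dist)
    obs <- as.integer(round(2 * w_pos))
    p_lo <- sum(dist[seq_len(obs + 1L)])
    p_hi <- sum(dist[(obs + 1L):length(dist)])
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = w_pos, p_value = p, flag = "")
}

#' Pairwise Wilcoxon signed-rank tests with Holm adjustment
#'
#' Applies [wilcoxon_signed_rank()] to every method pair and Holm-adjusts
#' the p-values across pairs. Pairs with all differences zero get p = 1
#' and a flag.
#'
#' @param metric_matrix Numeric methods x folds matrix with rownames.
#' @return data.frame with method_a, method_b, statistic, p_raw, p_holm,
#'   flag.
#' @export
wilcoxon_pairwise <- function(metric_matrix) {
  m <- as.matrix(metric_matrix)
  if (is.null(rownames(m))) rownames(m) <- paste0("method", seq_len(nrow(m)))
  pairs <- utils::combn(nrow(m), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    wt <- wilcoxon_signed_rank(m[i, ], m[j, ])
    data.frame(method_a = rownames(m)[i], method_b = rownames(m)[j],
               statistic = wt$statistic, p_raw = wt$p_value, flag = wt$flag)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out[, c("method_a", "method_b", "statistic", "p_raw", "p_holm", "flag")]
}

#' Evaluate a detector on held-out fields
#'
#' Runs [detect()] on every test field and aggregates the full metric
#' panel: pooled 3 x 4 confusion matrix, spurious count, [map_mar()] and a
#' pooled detection PR-AUC (a detection counts as correct when it matches a
#' same-class ground-truth nucleus at the IoU threshold; the recall
#' denominator is the total ground-truth nucleus count).
#'
#' @param model A trained `cyto_detector`.
#' @param fields List of `list(image, labels)` test elements.
#' @param iou_threshold Match threshold (default 0.5).
#' @return List with `confusion`, `spurious`, `map`, `mar`, `pr_auc`,
#'   `per_class` and the raw `detections`.
#' @export
evaluate_detector <- function(model, fields, iou_threshold = 0.5) {
  truth_sets <- lapply(fields, `[[`, "labels")
  detection_sets <- lapply(fields, function(f)
    detect(model, f$image, image_id = f$labels$image_id))
  cm <- empty_confusion(); spurious <- 0L
  pooled_scores <- numeric(0); pooled_ok <- logical(0); n_truth_total <- 0L
  for (i in seq_along(fields)) {
    mres <- match_detections(truth_sets[[i]], detection_sets[[i]],
                             iou_threshold = iou_threshold)
    cm <- cm + mres$confusion
    spurious <- spurious + mres$spurious
    n_truth_total <- n_truth_total + length(truth_sets[[i]]$annotations)
    tcls <- label_classes(truth_sets[[i]])
    ok <- rep(FALSE, length(detection_sets[[i]]))
    hit <- mres$assignment$detection
    for (ti in seq_along(hit)) {
      if (!is.na(hit[ti]) &&
          identical(detection_sets[[i]][[hit[ti]]]$cls, tcls[ti]))
        ok[hit[ti]] <- TRUE
    }
    pooled_scores <- c(pooled_scores,
                       vapply(detection_sets[[i]], `[[`, 0, "score"))
    pooled_ok <- c(pooled_ok, ok)
  }
  mm <- map_mar(truth_sets, detection_sets, iou_threshold)
  pr <- if (length(pooled_scores) > 0L && n_truth_total > 0L)
    average_precision(pooled_scores, pooled_ok, n_truth_total)$ap else 0
  list(confusion = cm, spurious = spurious, map = mm$map, mar = mm$mar,
       per_class = mm$per_class, pr_auc = pr, detections = detection_sets)
}
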