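# Mask R-CNN style loss components, exposed as standalone verified
# functions: the RPN objectness + box-regression loss, the class-weighted
# cross-entropy used for the n-category head, the smooth-L1 box loss, and
# the mask branch's average binary cross-entropy. Also the class-imbalance
# helpers (inverse-frequency weights, positive-image oversampling).

.EPS_LOG <- 1e-12

#' Smooth-L1 (Huber-style) robust loss
#'
#' `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise; continuous and
#' nonnegative. Vectorized.
#'
#' @param x Numeric vector.
#' @return Elementwise loss values.
#' @export
smooth_l1 <- function(x) {
  stopifnot(all(is.finite(x)))
  ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
}

#' Class-weighted cross-entropy classification loss
#'
#' `-sum_c w_c y_c log p_c` over the class set: zero iff the predicted
#' distribution puts all mass on the true class, and linear in the true
#' class's weight. Probabilities are clamped at `1e-12` inside the log
#' (with a warning when the clamp engages).
#'
#' @param p Predicted class-probability vector (sums to 1).
#' @param y One-hot truth vector of the same length.
#' @param w Strictly positive class weights (default all 1).
#' @return Scalar loss.
#' @export
classification_loss <- function(p, y, w = rep(1, length(p))) {
  if (abs(sum(p) - 1) > 1e-6) stop("p must sum to 1")
  if (!all(y %in% c(0, 1)) || sum(y) != 1) stop("y must be one-hot")
  if (any(w <= 0)) stop("class weights must be strictly positive")
  if (length(unique(c(length(p), length(y), length(w)))) != 1L)
    stop("p, y, w must have equal length")
  if (p[y == 1] < .EPS_LOG)
    warning("true-class probability clamped at 1e-12")
  -sum(w * y * log(pmax(p, .EPS_LOG)))
}

#' RPN loss: objectness cross-entropy plus gated box regression
#'
#' The two-term region-proposal loss
#' `(1/N_cls) sum_i L_cls(p_i, p_i*) + (lambda/N_reg) sum_i p_i* L_reg(t_i, t_i*)`
#' where `L_cls` is binary cross-entropy on anchor objectness and `L_reg`
#' is the summed [smooth_l1()] over the 4 box parameters. The regression
#' term is activated only for positive anchors (`p_i* = 1`), so box
#' parameters of negative anchors never influence the loss.
#'
#' @param p Predicted objectness probabilities, one per anchor.
#' @param p_star Ground-truth indicators in `{0, 1}`.
#' @param t Predicted box parameters, `n x 4` matrix.
#' @param t_star Ground-truth box parameters, `n x 4` matrix.
#' @param lambda Balance weight (default 1).
#' @param n_cls Classification normalizer (default: anchor count).
#' @param n_reg Regression normalizer (default: positive-anchor count, or 1
#'   when there are no positives so the zero regression sum stays defined).
#' @return List with `cls_term`, `reg_term` and `total`.
#' @export
rpn_loss <- function(p, p_star, t, t_star, lambda = 1,
                     n_cls = length(p), n_reg = max(1, sum(p_star))) {
  t <- as.matrix(t); t_star <- as.matrix(t_star)
  if (length(p) != length(p_star) || nrow(t) != length(p) || nrow(t_star) != length(p))
    stop("anchor arrays must have equal length")
  if (!all(p_star %in% c(0, 1))) stop("p_star entries must be 0 or 1")
  if (n_cls <= 0 || n_reg <= 0) stop("N_cls and N_reg must be positive")
  pc <- pmin(pmax(p, .EPS_LOG), 1 - .EPS_LOG)
  l_cls <- -(p_star * log(pc) + (1 - p_star) * log(1 - pc))
  l_reg <- rowSums(smooth_l1(t - t_star))
  cls_term <- sum(l_cls) / n_cls
  reg_term <- lambda * sum(p_star * l_reg) / n_reg
  list(cls_term = cls_term, reg_term = reg_term, total = cls_term + reg_term)
}

#' Mask branch loss: average binary cross-entropy
#'
#' @param pred Predicted per-pixel foreground probabilities.
#' @param truth Binary ground-truth mask (same shape).
#' @return Mean binary cross-entropy over mask pixels.
#' @export
mask_bce <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth shapes disagree")
  if (!all(truth %in% c(0, 1))) stop("truth mask must be binary")
  pc <- pmin(pmax(as.numeric(pred), .EPS_LOG), 1 - .EPS_LOG)
  tr <- as.numeric(truth)
  mean(-(tr * log(pc) + (1 - tr) * log(1 - pc)))
}

#' Total detection loss
#'
#' Sum of the classification, box-regression and mask branch losses.
#'
#' @param l_cls,l_reg,l_mask Finite component losses.
#' @return Their sum.
#' @export
total_loss <- function(l_cls, l_reg, l_mask) {
  stopifnot(is.finite(l_cls), is.finite(l_reg), is.finite(l_mask))
  l_cls + l_reg + l_mask
}

#' Inverse-frequency class weights
#'
#' Weights proportional to inverse class frequency, normalized so the
#' most frequent class gets weight 1, then capped. Under-represented
#' abnormal classes thus receive higher weight in the classification loss.
#'
#' @param counts Named or ordered counts for (yin, yin-yang, yang); all
#'   must be positive.
#' @param cap Maximum weight (default 100).
#' @return Numeric weight vector, same names/order as `counts`.
#' @export
compute_class_weights <- function(counts, cap = 100) {
  counts <- as.numeric(counts)
  if (any(counts <= 0))
    stop("zero count for a class: oversample that class before computing weights")
  w <- (1 / counts) / min(1 / counts)
  pmin(w, cap)
}

#' Oversample images containing abnormal cells
#'
#' Replicates images that contain at least one yin-yang or yang annotation
#' (round-robin, preserving order) until the abnormal-image fraction
#' reaches `target_ratio`. All original images are retained.
#'
#' @param fields List of `list(image, labels)` training elements.
#' @param target_ratio Desired minimum fraction of abnormal-containing
#'   images.
#' @return The resampled list (originals first, appended replicas after).
#' @export
oversample_positives <- function(fields, target_ratio = 0.5) {
  is_pos <- vapply(fields, function(f) {
    any(label_classes(f$labels) %in% c("yin-yang", "yang"))
  }, TRUE)
  if (!any(is_pos)) stop("no images contain abnormal cells; cannot oversample")
  n_pos <- sum(is_pos); n_tot <- length(fields)
  if (n_pos / n_tot >= target_ratio) return(fields)
  pos_idx <- which(is_pos)
  out <- fields
  k <- 0L
  while ((n_pos + k) / (n_tot + k) < target_ratio) {
    k <- k + 1L
    out[[n_tot + k]] <- fields[[pos_idx[(k - 1L) %% length(pos_idx) + 1L]]]
  }
  out
}
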