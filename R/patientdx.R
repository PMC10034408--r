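# Patient-level stage: aggregate per-patient nucleus classifications into
# seven features and train/evaluate four classifiers with stratified
# 10-fold cross-validation.

.PATIENT_FEATURES <- c("age", "yin", "yin_yang", "yang", "yang_ratio",
                       "combined_yang", "combined_yang_ratio")

#' Extract the seven patient-level features
#'
#' From a patient's classified cell counts: age, the three per-class
#' counts, the diseased-cell fraction `yang_ratio = yang / total`, the
#' combined abnormal count `combined_yang = yin_yang + yang` and its
#' fraction of the total.
#'
#' @param x Either a named count vector/list with entries `yin`,
#'   `yin-yang`/`yin_yang`, `yang`, or a list of detections (elements with
#'   a `cls` field), which are tallied.
#' @param age Patient age in years.
#' @return One-row data.frame with the seven feature columns.
#' @export
extract_features <- function(x, age) {
  if (is.list(x) && length(x) > 0 && !is.null(x[[1]]$cls)) {
    cls <- vapply(x, `[[`, "", "cls")
    counts <- table(factor(cls, levels = .CLASSES))
    yin <- counts[["yin"]]; yy <- counts[["yin-yang"]]; yang <- counts[["yang"]]
  } else {
    xx <- unlist(x)
    names(xx) <- gsub("-", "_", names(xx))
    for (f in c("yin", "yin_yang", "yang"))
      if (!f %in% names(xx)) stop(sprintf("missing count '%s'", f))
    yin <- xx[["yin"]]; yy <- xx[["yin_yang"]]; yang <- xx[["yang"]]
  }
  total <- yin + yy + yang
  if (total <= 0) stop("zero total cell count: ratios undefined")
  data.frame(age = age, yin = yin, yin_yang = yy, yang = yang,
             yang_ratio = yang / total, combined_yang = yy + yang,
             combined_yang_ratio = (yy + yang) / total)
}

#' Patient feature table from a synthetic cohort
#'
#' Sums each patient's per-field class counts and applies
#' [extract_features()].
#'
#' @param cohort Result of [generate_cohort()].
#' @return data.frame with patient_id, the seven features and `label`.
#' @export
cohort_features <- function(cohort) {
  agg <- stats::aggregate(cbind(yin, yin_yang, yang) ~ patient_id,
                          data = cohort$fields, FUN = sum)
  agg <- agg[match(cohort$patients$patient_id, agg$patient_id), ]
  feats <- do.call(rbind, lapply(seq_len(nrow(agg)), function(i)
    extract_features(c(yin = agg$yin[i], yin_yang = agg$yin_yang[i],
                       yang = agg$yang[i]), age = cohort$patients$age[i])))
  cbind(data.frame(patient_id = cohort$patients$patient_id), feats,
        data.frame(label = cohort$patients$label))
}

stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

fit_patient_model <- function(method, X, y, seed) {
  with_seed(seed, switch(
    method,
    logistic = suppressWarnings(
      stats::glm(y ~ ., data = data.frame(X, y = y), family = stats::binomial())),
    rf = randomForest::randomForest(X, y, ntree = 500, importance = TRUE),
    svm = e1071::svm(X, y, kernel = "radial", probability = TRUE, scale = TRUE),
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X),
                                     label = as.numeric(y == "positive"))
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = 3, eta = 0.3, nthread = 1),
                         data = dtrain, nrounds = 50, verbose = 0)
    },
    stop(sprintf("unknown method '%s'", method))))
}

predict_patient_model <- function(method, model, X) {
  switch(method,
         logistic = unname(predict(model, newdata = data.frame(X),
                                   type = "response")),
         rf = unname(predict(model, X, type = "prob")[, "positive"]),
         svm = {
           pr <- predict(model, X, probability = TRUE)
           unname(attr(pr, "probabilities")[, "positive"])
         },
         xgb = unname(predict(model, xgboost::xgb.DMatrix(as.matrix(X)))))
}

fold_metrics <- function(prob, y_true, threshold = 0.5) {
  pred <- ifelse(prob >= threshold, "positive", "normal")
  tp <- sum(pred == "positive" & y_true == "positive")
  tn <- sum(pred == "normal" & y_true == "normal")
  fp <- sum(pred == "positive" & y_true == "normal")
  fn <- sum(pred == "normal" & y_true == "positive")
  auc <- if (length(unique(y_true)) < 2L) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(response = y_true, predictor = prob,
                                   levels = c("normal", "positive"),
                                   direction = "<", quiet = TRUE)))
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  fg <- f1_gmean(if (is.na(prec)) 0 else prec,
                 if (is.na(sens)) 0 else sens,
                 if (is.na(spec)) 0 else spec)
  data.frame(auc = auc, accuracy = (tp + tn) / length(y_true),
             specificity = spec, sensitivity = sens, ppv = prec, npv = npv,
             f1 = fg$f1, gmean = fg$gmean)
}

#' Train and cross-validate the patient classifiers
#'
#' Fits each requested learner (logistic regression, random forest, RBF
#' SVM, gradient-boosted trees) under stratified k-fold cross-validation
#' and reports per-fold ROC AUC, accuracy, specificity, sensitivity,
#' PPV/NPV, F1 and G-mean at the 0.5 probability threshold, together with
#' final full-data fits and (for the tree ensembles) normalized feature
#' importances.
#'
#' @param features Feature data.frame containing the seven
#'   patient-feature columns.
#' @param labels Character/factor outcomes (`"normal"` / `"positive"`).
#' @param methods Subset of `c("logistic", "rf", "svm", "xgb")`.
#' @param cv_folds Number of folds (default 10); each class must have at
#'   least this many patients.
#' @param seed Integer seed (fold assignment and stochastic learners).
#' @return List with `per_fold` (long data.frame), `summary` (mean and sd
#'   per method and metric), `models`, `importances` and `folds`.
#' @export
train_patient_models <- function(features, labels,
                                 methods = c("logistic", "rf", "svm", "xgb"),
                                 cv_folds = 10L, seed = 1L) {
  methods <- match.arg(methods, c("logistic", "rf", "svm", "xgb"),
                       several.ok = TRUE)
  y <- factor(as.character(labels), levels = c("normal", "positive"))
  if (any(is.na(y))) stop("labels must be 'normal' or 'positive'")
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  if (min(table(y)) < cv_folds)
    stop(sprintf("need >= %d patients per class for %d-fold CV",
                 cv_folds, cv_folds))
  X <- features[, .PATIENT_FEATURES]
  fold <- stratified_folds(as.character(y), cv_folds, derive_seed(seed, "folds"))
  per_fold <- list()
  for (method in methods) {
    for (k in seq_len(cv_folds)) {
      tr <- fold != k; te <- fold == k
      fit <- fit_patient_model(method, X[tr, , drop = FALSE], y[tr],
                               derive_seed(seed, method, k))
      prob <- predict_patient_model(method, fit, X[te, , drop = FALSE])
      fm <- fold_metrics(prob, as.character(y[te]))
      per_fold[[length(per_fold) + 1L]] <-
        cbind(data.frame(method = method, fold = k), fm)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- setdiff(names(per_fold), c("method", "fold"))
  summary <- do.call(rbind, lapply(split(per_fold, per_fold$method), function(d) {
    means <- vapply(d[metric_cols], mean, 0, na.rm = TRUE)
    sds <- vapply(d[metric_cols], stats::sd, 0, na.rm = TRUE)
    out <- data.frame(method = d$method[1])
    for (mc in metric_cols) {
      out[[paste0(mc, "_mean")]] <- means[[mc]]
      out[[paste0(mc, "_sd")]] <- sds[[mc]]
    }
    out
  }))
  summary <- summary[match(methods, summary$method), ]
  rownames(summary) <- NULL
  models <- lapply(methods, function(m)
    fit_patient_model(m, X, y, derive_seed(seed, m, "final")))
  names(models) <- methods
  importances <- list()
  for (m in intersect(methods, c("rf", "xgb")))
    importances[[m]] <- rank_feature_importance(models[[m]])
  list(per_fold = per_fold, summary = summary, models = models,
       importances = importances, folds = fold)
}

#' Normalized feature importances from a tree-ensemble model
#'
#' Split-gain importances (xgboost Gain, random-forest mean Gini decrease)
#' over the seven patient features, normalized to sum to 1; features the
#' ensemble never used get importance 0.
#'
#' @param model A fitted random forest or xgboost booster from
#'   [train_patient_models()].
#' @return Named numeric vector over the seven features, summing to 1.
#' @export
rank_feature_importance <- function(model) {
  if (inherits(model, "randomForest")) {
    imp <- randomForest::importance(model)[, "MeanDecreaseGini"]
    v <- stats::setNames(rep(0, length(.PATIENT_FEATURES)), .PATIENT_FEATURES)
    v[names(imp)] <- imp
  } else if (inherits(model, "xgb.Booster")) {
    imp <- xgboost::xgb.importance(model = model)
    v <- stats::setNames(rep(0, length(.PATIENT_FEATURES)), .PATIENT_FEATURES)
    v[imp$Feature] <- imp$Gain
  } else {
    stop("rank_feature_importance requires a tree-ensemble model")
  }
  if (sum(v) <= 0) stop("model exposes no split-gain importance")
  v / sum(v)
}
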