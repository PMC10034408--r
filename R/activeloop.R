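# Conventional single-round (T1) vs. iterative pre-label-and-revise
# active-learning (A1..Ak) training protocols, with an annotation-cost
# ledger and per-round held-out evaluation.

#' Protocol configuration
#'
#' @param strategy `"conventional"`, `"active"` or `"both"`.
#' @param round_sizes Active-learning batch sizes per round (default the
#'   100/200/150 three-iteration design).
#' @param test_size Held-out test images (default 50), disjoint from every
#'   batch and fixed across rounds and strategies for a given seed.
#' @param seed Root seed: drives the test split, batch order, oracle
#'   streams and detector training.
#' @param oracle An [oracle_spec()] (simulated pathologist).
#' @param detector A [detector_config()].
#' @param cumulative Later rounds train on all revised data so far
#'   (default); `FALSE` trains on the newest batch only.
#' @return Object of class `protocol_config`.
#' @export
protocol_config <- function(strategy = c("both", "conventional", "active"),
                            round_sizes = c(100L, 200L, 150L),
                            test_size = 50L, seed = 1L,
                            oracle = oracle_spec(),
                            detector = detector_config(),
                            cumulative = TRUE) {
  strategy <- match.arg(strategy)
  if (length(round_sizes) < 1L) stop("round_sizes must be nonempty")
  structure(list(strategy = strategy, round_sizes = as.integer(round_sizes),
                 test_size = as.integer(test_size), seed = as.integer(seed),
                 oracle = oracle, detector = detector,
                 cumulative = isTRUE(cumulative)),
            class = "protocol_config")
}

# seeded test/pool split shared by both strategies
protocol_split <- function(n_images, config) {
  if (config$test_size >= n_images)
    stop("test_size must be smaller than the dataset")
  with_seed(derive_seed(config$seed, "split"), {
    test_idx <- sort(sample(n_images, config$test_size))
    pool <- setdiff(seq_len(n_images), test_idx)
    pool <- sample(pool)          # batch order for the active rounds
    list(test = test_idx, pool = pool)
  })
}

manual_cost <- function(label_sets, oracle) {
  n_ann <- sum(vapply(label_sets, function(l) length(l$annotations), 0L))
  list(n_draw = n_ann, n_fix_label = 0L, n_fix_spurious = 0L,
       cost_draw = oracle$cost_draw, cost_fix = oracle$cost_fix,
       total = n_ann * oracle$cost_draw)
}

#' Run the conventional single-round protocol (model T1)
#'
#' All non-test images are labeled fully manually (every annotation is
#' charged one draw cost) and a single detector is trained on them.
#'
#' @param dataset List of `list(image, labels)` elements with ground truth.
#' @param config A [protocol_config()].
#' @return List with `model`, `log` (a one-element round log) and
#'   `test_idx`.
#' @export
run_conventional <- function(dataset, config = protocol_config()) {
  sp <- protocol_split(length(dataset), config)
  train_idx <- sort(sp$pool)
  if (length(train_idx) < 4 * config$test_size)
    warning(sprintf("small training set (%d images)", length(train_idx)))
  train_fields <- dataset[train_idx]
  cost <- manual_cost(lapply(train_fields, `[[`, "labels"), config$oracle)
  model <- train_detector(train_fields, config$detector,
                          seed = derive_seed(config$seed, "T1"))
  metrics <- evaluate_detector(model, dataset[sp$test])
  log <- list(list(round = 1L, model_id = "T1", image_idx = train_idx,
                   labels = lapply(train_fields, `[[`, "labels"),
                   cost = cost, metrics = metrics[c("map", "mar", "pr_auc")],
                   confusion = metrics$confusion))
  list(model = model, log = log, test_idx = sp$test)
}

#' Run the iterative active-learning protocol (models A1..Ak)
#'
#' Round 1 is fully manual on the first batch. Each later round pre-labels
#' its batch with the previous round's model, passes the pre-labels through
#' the simulated pathologist ([simulate_revision()]), and trains the next
#' model warm-started from the previous one on the cumulative (or
#' batch-only) revised data. Every round is evaluated on the fixed test
#' set.
#'
#' @param dataset List of `list(image, labels)` elements with ground truth.
#' @param config A [protocol_config()].
#' @return List with `models` (one per round), `log` (per-round records:
#'   batch indices, revised labels, cost ledger, test metrics) and
#'   `test_idx`.
#' @export
run_active <- function(dataset, config = protocol_config()) {
  sp <- protocol_split(length(dataset), config)
  if (sum(config$round_sizes) > length(sp$pool))
    stop("round_sizes exceed the number of available images")
  offsets <- c(0L, cumsum(config$round_sizes))
  models <- list(); logs <- list()
  cum_fields <- list()
  prev_model <- NULL
  for (r in seq_along(config$round_sizes)) {
    batch_idx <- sp$pool[(offsets[r] + 1L):offsets[r + 1L]]
    batch <- dataset[batch_idx]
    if (r == 1L) {
      revised <- lapply(batch, `[[`, "labels")
      cost <- manual_cost(revised, config$oracle)
    } else {
      revised <- vector("list", length(batch))
      n_draw <- 0L; n_fix_label <- 0L; n_fix_spurious <- 0L
      for (b in seq_along(batch)) {
        pre <- detect(prev_model, batch[[b]]$image,
                      image_id = batch[[b]]$labels$image_id)
        rv <- simulate_revision(batch[[b]]$labels, pre, config$oracle,
                                .seed = derive_seed(config$seed, "oracle", r, b))
        revised[[b]] <- rv$revised
        n_draw <- n_draw + rv$cost$n_draw
        n_fix_label <- n_fix_label + rv$cost$n_fix_label
        n_fix_spurious <- n_fix_spurious + rv$cost$n_fix_spurious
      }
      cost <- list(n_draw = n_draw, n_fix_label = n_fix_label,
                   n_fix_spurious = n_fix_spurious,
                   cost_draw = config$oracle$cost_draw,
                   cost_fix = config$oracle$cost_fix,
                   total = n_draw * config$oracle$cost_draw +
                     (n_fix_label + n_fix_spurious) * config$oracle$cost_fix)
    }
    batch_fields <- lapply(seq_along(batch), function(b)
      list(image = batch[[b]]$image, labels = revised[[b]]))
    cum_fields <- c(cum_fields, batch_fields)
    train_on <- if (config$cumulative) cum_fields else batch_fields
    model <- train_detector(train_on, config$detector,
                            seed = derive_seed(config$seed, "A", r),
                            init = prev_model)
    metrics <- evaluate_detector(model, dataset[sp$test])
    models[[r]] <- model
    logs[[r]] <- list(round = r, model_id = paste0("A", r),
                      image_idx = batch_idx, labels = revised, cost = cost,
                      metrics = metrics[c("map", "mar", "pr_auc")],
                      confusion = metrics$confusion)
    prev_model <- model
  }
  list(models = models, log = logs, test_idx = sp$test)
}

# fraction of training annotations whose class agrees with a matched
# ground-truth nucleus (IoU >= 0.5)
label_agreement <- function(labels, truth_sets) {
  agree <- 0L; total <- 0L
  for (i in seq_along(labels)) {
    lab <- labels[[i]]; tr <- truth_sets[[i]]
    total <- total + length(lab$annotations)
    if (length(lab$annotations) == 0L) next
    dets <- lapply(seq_along(lab$annotations), function(j)
      list(image_id = lab$image_id, polygon = lab$annotations[[j]]$polygon,
           cls = lab$annotations[[j]]$cls, score = 1))
    m <- match_detections(tr, dets, iou_threshold = 0.5)
    tcls <- label_classes(tr)
    for (ti in seq_along(m$assignment$detection)) {
      di <- m$assignment$detection[ti]
      if (!is.na(di) && identical(dets[[di]]$cls, tcls[ti]))
        agree <- agree + 1L
    }
  }
  if (total == 0L) return(NA_real_)
  agree / total
}

#' Compare the conventional and active protocols
#'
#' Builds a per-model comparison table (T1, A1..Ak): images used,
#' cumulative annotation cost, test mAP/mAR/PR-AUC and the
#' training-label-vs-truth agreement rate, plus the overall cost ratio
#' conventional/active.
#'
#' @param conventional Result of [run_conventional()].
#' @param active Result of [run_active()].
#' @param dataset The dataset both were run on (for label agreement).
#' @return List with `table` (data.frame, one row per model) and
#'   `cost_ratio`.
#' @export
compare_protocols <- function(conventional, active, dataset) {
  if (!identical(conventional$test_idx, active$test_idx))
    stop("protocols were evaluated on different test sets")
  rows <- list()
  conv_log <- conventional$log[[1]]
  truth_conv <- lapply(dataset[conv_log$image_idx], `[[`, "labels")
  rows[[1]] <- data.frame(
    model = "T1", n_images = length(conv_log$image_idx),
    cum_cost = conv_log$cost$total,
    map = conv_log$metrics$map, mar = conv_log$metrics$mar,
    pr_auc = conv_log$metrics$pr_auc,
    label_agreement = label_agreement(conv_log$labels, truth_conv))
  cum_cost <- 0; cum_n <- 0L
  for (r in seq_along(active$log)) {
    lg <- active$log[[r]]
    cum_cost <- cum_cost + lg$cost$total
    cum_n <- cum_n + length(lg$image_idx)
    truth_r <- lapply(dataset[lg$image_idx], `[[`, "labels")
    rows[[r + 1L]] <- data.frame(
      model = lg$model_id, n_images = cum_n, cum_cost = cum_cost,
      map = lg$metrics$map, mar = lg$metrics$mar, pr_auc = lg$metrics$pr_auc,
      label_agreement = label_agreement(lg$labels, truth_r))
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       cost_ratio = tab$cum_cost[1] / tab$cum_cost[nrow(tab)])
}
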