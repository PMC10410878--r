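# Threshold-based and threshold-free evaluation: confusion counts,
# accuracy/precision/recall/F1, ROC AUC (Mann-Whitney, exact tie handling)
# and PR AUC (step-wise interpolation), plus dataset-level evaluation,
# cross-cell-type transfer, and capsule-feature export.

#' Confusion counts
#'
#' Standard 2x2 table with the loop class (1) as positive.
#'
#' @param truth Binary vector of true labels.
#' @param estimate Binary vector of predicted classes.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate lengths differ", call. = FALSE)
  }
  if (!all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    stop("truth and estimate must be binary (0/1)", call. = FALSE)
  }
  tibble::tibble(
    tp = sum(truth == 1 & estimate == 1),
    tn = sum(truth == 0 & estimate == 0),
    fp = sum(truth == 0 & estimate == 1),
    fn = sum(truth == 1 & estimate == 0)
  )
}

#' Scalar classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, and F1 (harmonic mean of precision and recall). A zero
#' denominator yields `NA` (an explicit undefined marker) rather than a
#' silent zero.
#'
#' @param counts A one-row tibble from [confusion_counts()].
#' @return A one-row tibble with `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("no samples to evaluate", call. = FALSE)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(accuracy = (tp + tn) / total, precision = precision,
                 recall = recall, f1 = f1)
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' Computes `P(score_pos > score_neg) + 0.5 P(tie)` exactly via midranks —
#' no binning, deterministic, and invariant under strictly monotone score
#' transforms.
#'
#' @param truth Binary vector of true labels (both classes required).
#' @param score Numeric ranking scores (higher = more loop-like).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(truth, score) {
  stopifnot(length(truth) == length(score), all(truth %in% c(0, 1)))
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC AUC needs both classes present", call. = FALSE)
  }
  r <- rank(score)  # midranks handle ties
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC (step-wise interpolation)
#'
#' Area under the precision-recall step curve over all score thresholds:
#' thresholds sweep the distinct scores from high to low, and each increase
#' in recall contributes `delta_recall * precision` at that threshold
#' (step-wise, avoiding the optimism of linear PR interpolation).
#'
#' @inheritParams roc_auc
#' @return AUPR in `[0, 1]`.
#' @export
pr_auc <- function(truth, score) {
  pts <- pr_points(truth, score)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

# Precision/recall at every distinct threshold, high to low.
pr_points <- function(truth, score) {
  stopifnot(length(truth) == length(score), all(truth %in% c(0, 1)))
  n_pos <- sum(truth == 1)
  if (n_pos == 0L) stop("PR AUC needs at least one positive", call. = FALSE)
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  tp <- cumsum(truth == 1)
  fp <- cumsum(truth == 0)
  keep <- c(diff(score) != 0, TRUE)  # last index of each tie group
  tibble::tibble(threshold = score[keep],
                 recall = tp[keep] / n_pos,
                 precision = tp[keep] / (tp[keep] + fp[keep]))
}

# ROC curve points (FPR, TPR) at every distinct threshold.
roc_points <- function(truth, score) {
  stopifnot(length(truth) == length(score), all(truth %in% c(0, 1)))
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  tp <- cumsum(truth == 1); fp <- cumsum(truth == 0)
  keep <- c(diff(score) != 0, TRUE)
  tibble::tibble(threshold = score[keep],
                 fpr = fp[keep] / n_neg, tpr = tp[keep] / n_pos)
}

#' Assemble a full metrics report
#'
#' @param truth Binary labels.
#' @param score Ranking scores (loop-capsule lengths).
#' @param estimate Predicted classes (argmax rule; see [capsule_decision()]).
#' @return An object of class `loop_metrics`: confusion counts, scalar
#'   metrics, `auc`, `aupr`, the score table, and ROC/PR curve points.
#' @export
metrics_report <- function(truth, score, estimate) {
  counts <- confusion_counts(truth, estimate)
  scalars <- classification_metrics(counts)
  structure(
    list(counts = counts, scalars = scalars,
         auc = roc_auc(truth, score), aupr = pr_auc(truth, score),
         scores = tibble::tibble(label = as.integer(truth), score = score,
                                 class = as.integer(estimate)),
         roc_curve = roc_points(truth, score),
         pr_curve = pr_points(truth, score)),
    class = "loop_metrics"
  )
}

#' Evaluate a fitted model on a dataset
#'
#' Scores every pair with [predict.capsnet_model()] (score = loop-capsule
#' length, class = argmax of the two capsule lengths) and assembles a
#' [metrics_report()]. Note the classification threshold is the argmax rule,
#' not `score > 0.5`; AUC/AUPR are threshold-free and unaffected.
#'
#' @param fit A `capsnet_fit`.
#' @param pairs A pair table or [encode_pairs()] result.
#' @return A `loop_metrics` object.
#' @export
evaluate_pairs <- function(fit, pairs) {
  pr <- predict(fit, pairs)
  metrics_report(pr$label, pr$score, pr$class)
}

#' @export
print.loop_metrics <- function(x, ...) {
  cat("<loop_metrics>\n")
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n", x$counts$tp, x$counts$tn,
              x$counts$fp, x$counts$fn))
  cat(sprintf("  Acc %.4f  Precision %s  Recall %s  F1 %s\n",
              x$scalars$accuracy,
              formatC(x$scalars$precision, digits = 4, format = "f"),
              formatC(x$scalars$recall, digits = 4, format = "f"),
              formatC(x$scalars$f1, digits = 4, format = "f")))
  cat(sprintf("  AUC %.4f  AUPR %.4f\n", x$auc, x$aupr))
  invisible(x)
}

#' Cross-cell-type transfer matrix
#'
#' Entry (i, j) is the AUC of the model trained on condition i evaluated on
#' condition j's dataset: the diagonal is each model on its own condition,
#' off-diagonals measure transfer.
#'
#' @param fits Named list of `capsnet_fit` objects (names = training
#'   conditions).
#' @param datasets Named list of pair tables or encoded datasets (names =
#'   evaluation conditions); must cover the same condition names.
#' @return A tibble of class `cross_cell_tbl` with columns
#'   `train_condition`, `eval_condition`, `auc`.
#' @export
cross_cell_auc <- function(fits, datasets) {
  if (length(fits) < 2L) stop("need at least 2 conditions", call. = FALSE)
  if (is.null(names(fits)) || is.null(names(datasets))) {
    stop("fits and datasets must be named by condition", call. = FALSE)
  }
  missing_ds <- setdiff(names(fits), names(datasets))
  if (length(missing_ds) > 0L) {
    stop("missing evaluation dataset(s) for condition(s): ",
         paste(missing_ds, collapse = ", "), call. = FALSE)
  }
  encoded <- lapply(datasets, function(d) {
    if (inherits(d, "encoded_pairs")) d else encode_pairs(d)
  })
  grid <- tidyr::expand_grid(train_condition = names(fits),
                             eval_condition = names(fits))
  grid$auc <- purrr::map2_dbl(grid$train_condition, grid$eval_condition,
    function(tr, ev) {
      pr <- predict(fits[[tr]], encoded[[ev]])
      roc_auc(pr$label, pr$score)
    })
  class(grid) <- c("cross_cell_tbl", class(grid))
  grid
}

#' Pivot a cross-cell tibble to a labeled matrix
#'
#' @param x A `cross_cell_tbl` from [cross_cell_auc()].
#' @return A square numeric matrix, rows = training condition, columns =
#'   evaluation condition.
#' @export
cross_cell_matrix <- function(x) {
  conds <- unique(x$train_condition)
  m <- matrix(NA_real_, length(conds), length(conds),
              dimnames = list(train = conds, eval = conds))
  for (i in seq_len(nrow(x))) {
    m[x$train_condition[i], x$eval_condition[i]] <- x$auc[i]
  }
  m
}

#' Export per-sample features for visualization
#'
#' Supplies the input of an external 2-D projection (e.g. t-SNE): either the
#' flattened one-hot matrices of both branches (`layer = "input"`) or the
#' two digit-capsule vectors (`layer = "digit_caps"`, 16 values for the
#' default 2 x 8 capsules). Deterministic at inference.
#'
#' @param fit A `capsnet_fit` (ignored for `layer = "input"`).
#' @param pairs A pair table or encoded dataset.
#' @param layer `"digit_caps"` or `"input"`.
#' @param batch_size Forward-pass batch size.
#' @return A tibble: `id`, `label`, then the flattened feature columns
#'   (`v1`, `v2`, ...).
#' @export
export_embeddings <- function(fit, pairs, layer = c("digit_caps", "input"),
                              batch_size = 256L) {
  layer <- match.arg(layer)
  enc <- if (inherits(pairs, "encoded_pairs")) pairs else encode_pairs(pairs)
  if (layer == "input") {
    feats <- cbind(matrix(enc$x_a, nrow = enc$n), matrix(enc$x_b, nrow = enc$n))
  } else {
    stopifnot(inherits(fit, "capsnet_model"))
    jd <- fit$config$digit_caps_count * fit$config$digit_caps_dim
    feats <- matrix(0, enc$n, jd)
    for (chunk in split(seq_len(enc$n), ceiling(seq_len(enc$n) / batch_size))) {
      fwd <- capsnet_fwd(fit$params, fit$config,
                         enc$x_a[chunk, , , drop = FALSE],
                         enc$x_b[chunk, , , drop = FALSE], training = FALSE)
      feats[chunk, ] <- fwd$v
    }
  }
  colnames(feats) <- paste0("v", seq_len(ncol(feats)))
  dplyr::bind_cols(tibble::tibble(id = enc$id, label = enc$label),
                   tibble::as_tibble(feats))
}
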