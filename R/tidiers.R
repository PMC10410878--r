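# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted capsule network
#'
#' The per-epoch training history.
#'
#' @param x A `capsnet_fit`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `train_loss`, `val_loss`, `seconds`.
#' @method tidy capsnet_fit
#' @export
tidy.capsnet_fit <- function(x, ...) x$history

#' One-row summary of a fitted capsule network
#'
#' @param x A `capsnet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs run, best epoch and its
#'   validation loss, sizes of the train/validation splits, and the ablation
#'   switches.
#' @method glance capsnet_fit
#' @export
glance.capsnet_fit <- function(x, ...) {
  tibble::tibble(
    n_params = length(tree_flatten(x$params)$values),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    n_train = x$n_train,
    n_valid = x$n_valid,
    seq_len = x$config$seq_len,
    use_msc = x$config$use_msc,
    use_bigru = x$config$use_bigru
  )
}

#' Tidy an evaluation report
#'
#' @param x A `loop_metrics` object from [evaluate_pairs()] or
#'   [metrics_report()].
#' @param ... Unused.
#' @return A long tibble with columns `metric` and `value`.
#' @method tidy loop_metrics
#' @export
tidy.loop_metrics <- function(x, ...) {
  g <- glance(x)
  tidyr::pivot_longer(g, dplyr::everything(), names_to = "metric",
                      values_to = "value")
}

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.loop_metrics
#' @return A one-row tibble: confusion counts, accuracy, precision, recall,
#'   F1, AUC, AUPR and `n`.
#' @method glance loop_metrics
#' @export
glance.loop_metrics <- function(x, ...) {
  dplyr::bind_cols(
    x$counts, x$scalars,
    tibble::tibble(auc = x$auc, aupr = x$aupr,
                   n = sum(unlist(x$counts)))
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `capsnet_cv`.
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @method tidy capsnet_cv
#' @export
tidy.capsnet_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.capsnet_cv
#' @return Fold-averaged accuracy and AUC with standard deviations, plus the
#'   pooled-prediction AUC/AUPR.
#' @method glance capsnet_cv
#' @export
glance.capsnet_cv <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$folds),
    mean_accuracy = mean(x$folds$accuracy),
    sd_accuracy = stats::sd(x$folds$accuracy),
    mean_auc = mean(x$folds$auc),
    sd_auc = stats::sd(x$folds$auc),
    pooled_auc = x$pooled$auc,
    pooled_aupr = x$pooled$aupr
  )
}

#' Plot the training history of a fit
#'
#' @param object A `capsnet_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation margin loss per epoch, with the
#'   restored best epoch marked.
#' @method autoplot capsnet_fit
#' @export
autoplot.capsnet_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "split", values_to = "loss")
  h$split <- sub("_loss$", "", h$split)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "epoch", y = "margin loss", colour = NULL,
                  title = "Training history",
                  subtitle = sprintf("best epoch %d (validation loss %.4f)",
                                     object$best_epoch, object$best_val_loss)) +
    ggplot2::theme_minimal()
}

#' Plot ROC and PR curves of an evaluation
#'
#' @param object A `loop_metrics` object.
#' @param ... Unused.
#' @return A faceted ggplot with the ROC and precision-recall step curves.
#' @method autoplot loop_metrics
#' @export
autoplot.loop_metrics <- function(object, ...) {
  roc <- tibble::tibble(x = c(0, object$roc_curve$fpr),
                        y = c(0, object$roc_curve$tpr),
                        curve = sprintf("ROC (AUC = %.3f)", object$auc))
  pr <- tibble::tibble(x = object$pr_curve$recall,
                       y = object$pr_curve$precision,
                       curve = sprintf("PR (AUPR = %.3f)", object$aupr))
  ggplot2::ggplot(dplyr::bind_rows(roc, pr),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~curve) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-cell transfer matrix
#'
#' @param object A `cross_cell_tbl` from [cross_cell_auc()].
#' @param ... Unused.
#' @return A ggplot tile heatmap of AUC by training and evaluation condition.
#' @method autoplot cross_cell_tbl
#' @export
autoplot.cross_cell_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$eval_condition,
                               y = .data$train_condition,
                               fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$auc))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0.5, 1), oob = scales_squish) +
    ggplot2::labs(x = "evaluated on", y = "trained on", fill = "AUC") +
    ggplot2::theme_minimal()
}

# minimal squish (avoids a scales dependency)
scales_squish <- function(x, range = c(0, 1)) pmin(pmax(x, range[1]), range[2])

#' @importFrom rlang .data
NULL
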