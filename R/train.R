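# Optimization loop: Adam on the margin loss, early stopping on a stratified
# validation split, and ten-fold cross-validation orchestration.

#' Training configuration
#'
#' Defaults follow the published training protocol: Adam with batch size 64
#' and learning rate 5e-4, early stopping on the validation margin loss, and
#' ten-fold cross-validation. Patience, epoch cap and the validation
#' fraction are this package's choices (the protocol mandates early stopping
#' without naming them).
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early stopping: stop after this many consecutive epochs
#'   without improvement of the monitored validation loss; the best-epoch
#'   weights are restored.
#' @param validation_fraction Stratified fraction of the training set held
#'   out to monitor early stopping.
#' @param n_folds Folds for [crossval_capsnet()].
#' @param seed Master seed; shuffling, dropout and per-fold seeds derive
#'   from it.
#' @param verbose Print one line per epoch.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 5e-4,
                         max_epochs = 100L, patience = 10L,
                         validation_fraction = 0.1, n_folds = 10L,
                         seed = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 1L, learning_rate > 0,
            max_epochs >= 1L, patience >= 1L,
            validation_fraction > 0, validation_fraction < 1,
            n_folds >= 2L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# One master seed reproduces a whole experiment: sub-seeds are derived by a
# documented multiplicative hash, kept below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.double(seed) * 48271 + h * 16807) %% 2147483647)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(x, ...) x * 0
  list(m = tree_map2(zero, params, params),
       v = tree_map2(zero, params, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / corr1) / (sqrt(v / corr2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

# ---- splits ---------------------------------------------------------------

#' Stratified k-fold assignment
#'
#' Partitions indices into `k` folds of near-equal size whose class ratios
#' match the whole within one sample, deterministically for a seed. Every
#' index appears in exactly one fold.
#'
#' @param labels Binary label vector.
#' @param k Number of folds (`k <=` the size of the smaller class).
#' @param seed Seed for the shuffle.
#' @return An integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  stopifnot(all(labels %in% c(0, 1)))
  k <- as.integer(k)
  counts <- table(factor(labels, levels = c(0, 1)))
  if (any(counts == 0L)) stop("both classes must be present", call. = FALSE)
  if (k > min(counts)) {
    stop(sprintf("k = %d exceeds the smaller class count (%d)", k, min(counts)),
         call. = FALSE)
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    # deal fold ids cyclically, continuing the cycle across classes: per-class
    # fold counts differ by <= 1 (stratification) and, because remainders of
    # the two classes land on different folds, total sizes differ by <= 1 too
    offset <- 0L
    for (cl in c(0, 1)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

# Single stratified holdout; returns list(train, valid) index vectors.
stratified_holdout <- function(labels, fraction, seed) {
  valid <- integer(0)
  withr::with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- which(labels == cl)
      n_val <- max(1L, round(length(idx) * fraction))
      if (n_val >= length(idx)) {
        stop("validation split would exhaust a class; need more samples",
             call. = FALSE)
      }
      valid <- c(valid, sample(idx, n_val))
    }
  })
  if (length(unique(labels[-valid])) < 2L || length(unique(labels[valid])) < 2L) {
    stop("a class is empty in the training or validation split", call. = FALSE)
  }
  list(train = setdiff(seq_along(labels), valid), valid = sort(valid))
}

# Early-stop bookkeeping: index of the epoch whose weights should be kept,
# given the monitored per-epoch losses and a patience.
best_epoch_stop <- function(val_losses, patience) {
  best <- 1L; wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < val_losses[best]) {
      best <- e; wait <- 0L
    } else if (e > 1L) {
      wait <- wait + 1L
      if (wait >= patience) return(list(best = best, stopped_at = e))
    }
  }
  list(best = best, stopped_at = length(val_losses))
}

# Mean margin loss over a dataset at inference (no dropout), batched.
eval_loss <- function(params, cfg, enc, idx, batch_size = 256L) {
  total <- 0
  for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
    r <- capsnet_loss(params, cfg,
                      enc$x_a[chunk, , , drop = FALSE],
                      enc$x_b[chunk, , , drop = FALSE],
                      enc$label[chunk], training = FALSE, with_grads = FALSE)
    total <- total + r$loss * length(chunk)
  }
  total / length(idx)
}

# ---- single training run --------------------------------------------------

#' Train a capsule network on labeled sequence pairs
#'
#' Minimizes the margin loss with Adam. A stratified
#' `validation_fraction` of the data is held out to monitor early stopping;
#' training stops once the validation loss has not improved for
#' `patience` consecutive epochs and the best-epoch weights are restored.
#' Fully reproducible for a given `train_cfg$seed` (shuffling, dropout and
#' initialization are all seeded).
#'
#' @param pairs A pair table (see [validate_pairs()]) or an
#'   [encode_pairs()] result.
#' @param model_cfg A [caps_config()]; its `seq_len` must match the data.
#' @param train_cfg A [train_config()].
#' @return An object of class `capsnet_fit` (also `capsnet_model`) with the
#'   trained `params`, configs, per-epoch `history` tibble, and `best_epoch`.
#' @export
fit_capsnet <- function(pairs, model_cfg = caps_config(),
                        train_cfg = train_config()) {
  enc <- if (inherits(pairs, "encoded_pairs")) pairs else encode_pairs(pairs)
  if (enc$seq_len != model_cfg$seq_len) {
    stop(sprintf("data L = %d but model seq_len = %d", enc$seq_len,
                 model_cfg$seq_len), call. = FALSE)
  }
  model_cfg$seed <- derive_seed(train_cfg$seed, "init")
  model <- capsnet_init_model(model_cfg)
  params <- model$params
  split <- stratified_holdout(enc$label, train_cfg$validation_fraction,
                              derive_seed(train_cfg$seed, "holdout"))
  opt <- adam_init(params)
  history <- vector("list", train_cfg$max_epochs)
  best_params <- params
  best_loss <- Inf
  wait <- 0L
  best_epoch <- 0L
  n_train <- length(split$train)
  for (epoch in seq_len(train_cfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    epoch_seed <- derive_seed(train_cfg$seed, paste0("epoch", epoch))
    train_loss <- withr::with_seed(epoch_seed, {
      order_idx <- sample(split$train)
      batches <- split(order_idx, ceiling(seq_along(order_idx) /
                                            train_cfg$batch_size))
      tot <- 0
      for (bi in batches) {
        r <- capsnet_loss(params, model_cfg,
                          enc$x_a[bi, , , drop = FALSE],
                          enc$x_b[bi, , , drop = FALSE],
                          enc$label[bi], training = TRUE, with_grads = TRUE)
        st <- adam_step(params, r$grads, opt, train_cfg$learning_rate)
        params <- st$params
        opt <- st$state
        tot <- tot + r$loss * length(bi)
      }
      tot / n_train
    })
    val_loss <- eval_loss(params, model_cfg, enc, split$valid)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      seconds = proc.time()[["elapsed"]] - t0
    )
    if (train_cfg$verbose) {
      message(sprintf("epoch %3d  train %.4f  valid %.4f", epoch,
                      train_loss, val_loss))
    }
    if (val_loss < best_loss) {
      best_loss <- val_loss
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$patience) break
    }
  }
  history <- dplyr::bind_rows(history[!vapply(history, is.null, logical(1))])
  structure(
    list(params = best_params, config = model_cfg, shapes = model$shapes,
         train_config = train_cfg, history = history,
         best_epoch = best_epoch, best_val_loss = best_loss,
         n_train = n_train, n_valid = length(split$valid)),
    class = c("capsnet_fit", "capsnet_model")
  )
}

#' Predict loop scores for sequence pairs
#'
#' Runs the trained network at inference (deterministic: no dropout) and
#' returns, per pair, the two digit-capsule lengths, the ranking `score`
#' (= loop-capsule length), and the argmax `class`.
#'
#' @param object A `capsnet_fit` (or initialized `capsnet_model`).
#' @param new_data A pair table or [encode_pairs()] result.
#' @param batch_size Internal batch size for the forward pass.
#' @param ... Unused.
#' @return A tibble with columns `id`, `label` (if present), `len_no_loop`,
#'   `len_loop`, `score`, `class`.
#' @export
predict.capsnet_model <- function(object, new_data, batch_size = 256L, ...) {
  enc <- if (inherits(new_data, "encoded_pairs")) new_data else
    encode_pairs(new_data)
  if (enc$seq_len != object$config$seq_len) {
    stop(sprintf("data L = %d but model seq_len = %d", enc$seq_len,
                 object$config$seq_len), call. = FALSE)
  }
  lengths <- matrix(0, enc$n, 2L)
  for (chunk in split(seq_len(enc$n), ceiling(seq_len(enc$n) / batch_size))) {
    fwd <- capsnet_fwd(object$params, object$config,
                       enc$x_a[chunk, , , drop = FALSE],
                       enc$x_b[chunk, , , drop = FALSE],
                       training = FALSE)
    lengths[chunk, ] <- fwd$lengths
  }
  dec <- capsule_decision(lengths)
  tibble::tibble(id = enc$id, label = enc$label,
                 len_no_loop = lengths[, 1L], len_loop = lengths[, 2L],
                 score = dec$score, class = dec$class)
}

# ---- cross-validation -----------------------------------------------------

#' Stratified k-fold cross-validation
#'
#' Trains `n_folds` independent models, each evaluated on its held-out fold.
#' Per-fold seeds derive deterministically from the master seed. Reports both
#' fold-averaged metrics and a pooled-prediction AUC/AUPR (the protocol the
#' published tables use is unstated, so both are given).
#'
#' @inheritParams fit_capsnet
#' @return An object of class `capsnet_cv`: `folds` (per-fold metrics
#'   tibble), `fold_assignment`, `pooled` (metrics on pooled out-of-fold
#'   predictions), `predictions` (per-sample out-of-fold tibble), and the
#'   fitted models in `fits`.
#' @export
crossval_capsnet <- function(pairs, model_cfg = caps_config(),
                             train_cfg = train_config()) {
  enc <- if (inherits(pairs, "encoded_pairs")) pairs else encode_pairs(pairs)
  k <- train_cfg$n_folds
  fold <- stratified_folds(enc$label, k, derive_seed(train_cfg$seed, "folds"))
  fold_rows <- vector("list", k)
  fits <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    va_idx <- which(fold == f)
    fold_cfg <- train_cfg
    fold_cfg$seed <- derive_seed(train_cfg$seed, paste0("fold", f))
    fit <- fit_capsnet(encoded_subset(enc, tr_idx), model_cfg, fold_cfg)
    pr <- predict(fit, encoded_subset(enc, va_idx))
    pr$fold <- f
    rep <- metrics_report(pr$label, pr$score, pr$class)
    fold_rows[[f]] <- dplyr::mutate(glance(rep), fold = f, .before = 1L)
    fits[[f]] <- fit
    preds[[f]] <- pr
  }
  predictions <- dplyr::bind_rows(preds)
  pooled <- metrics_report(predictions$label, predictions$score,
                           predictions$class)
  structure(
    list(folds = dplyr::bind_rows(fold_rows), fold_assignment = fold,
         pooled = pooled, predictions = predictions, fits = fits,
         model_config = model_cfg, train_config = train_cfg),
    class = "capsnet_cv"
  )
}

#' @export
print.capsnet_cv <- function(x, ...) {
  cat(sprintf("<capsnet_cv> %d folds\n", nrow(x$folds)))
  cat(sprintf("  mean Acc %.4f  mean AUC %.4f (sd %.4f)  pooled AUC %.4f\n",
              mean(x$folds$accuracy), mean(x$folds$auc), stats::sd(x$folds$auc),
              x$pooled$auc))
  invisible(x)
}

#' Save / load a fitted model
#'
#' The checkpoint is a single RDS archive holding the weights and the full
#' model configuration used (self-describing), plus a format version.
#'
#' @param fit A `capsnet_fit`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `capsnet_fit` (load).
#' @export
save_capsnet <- function(fit, path) {
  stopifnot(inherits(fit, "capsnet_model"))
  saveRDS(list(format = "loopcaps-checkpoint-1", fit = fit), path)
  invisible(path)
}

#' @rdname save_capsnet
#' @export
load_capsnet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "loopcaps-checkpoint-1")) {
    stop("not a loopcaps checkpoint (or unsupported version)", call. = FALSE)
  }
  obj$fit
}
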