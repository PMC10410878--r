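# Optimization loop: early stopping, stratified splits, determinism, and
# cross-validation orchestration.

test_that("early-stopping rule stops after `patience` flat epochs and keeps the best", {
  r <- loopcaps:::best_epoch_stop(c(1.0, 0.9, 0.91, 0.92), patience = 2)
  expect_equal(r$best, 2L)
  expect_equal(r$stopped_at, 4L)
  # no plateau: runs to the end
  r2 <- loopcaps:::best_epoch_stop(c(1.0, 0.9, 0.8, 0.7), patience = 2)
  expect_equal(r2$best, 4L)
  expect_equal(r2$stopped_at, 4L)
  # patience >= run length never triggers
  r3 <- loopcaps:::best_epoch_stop(c(0.5, 0.6, 0.6), patience = 10)
  expect_equal(r3$best, 1L)
  expect_equal(r3$stopped_at, 3L)
})

test_that("stratified folds partition the data with matched class ratios", {
  labels <- rep(c(1, 0), each = 50)
  fold <- stratified_folds(labels, 10, seed = 4)
  expect_equal(sort(unique(fold)), 1:10)
  for (f in 1:10) {
    expect_equal(sum(fold == f), 10L)
    expect_equal(sum(fold == f & labels == 1), 5L)  # 5/5 in every fold
  }
  # randomized n and k: disjoint cover with near-equal sizes and ratios
  withr::with_seed(30, {
    for (rep in 1:10) {
      n1 <- sample(15:60, 1); n0 <- sample(15:60, 1)
      labels <- sample(rep(c(1, 0), c(n1, n0)))
      k <- sample(2:min(10, n1, n0), 1)
      fold <- stratified_folds(labels, k, seed = rep)
      expect_equal(length(fold), n1 + n0)            # coverage: every index
      expect_true(all(fold %in% 1:k))
      sizes <- tabulate(fold, k)
      expect_lte(diff(range(sizes)), 1L)             # near-equal sizes
      pos_sizes <- tabulate(fold[labels == 1], k)
      expect_lte(diff(range(pos_sizes)), 1L)         # stratification
    }
  })
  # 103 samples, k = 10: sizes differ by at most 1
  labels103 <- rep(c(1, 0), c(52, 51))
  sizes <- tabulate(stratified_folds(labels103, 10, seed = 1), 10)
  expect_lte(diff(range(sizes)), 1L)
  expect_error(stratified_folds(rep(c(1, 0), c(3, 50)), 10),
               "exceeds the smaller class")
  expect_error(stratified_folds(rep(1, 10), 2), "both classes")
})

test_that("fold assignment is deterministic for a seed", {
  labels <- rep(c(1, 0), each = 30)
  expect_identical(stratified_folds(labels, 5, seed = 7),
                   stratified_folds(labels, 5, seed = 7))
  expect_false(identical(stratified_folds(labels, 5, seed = 7),
                         stratified_folds(labels, 5, seed = 8)))
})

test_that("training reduces the margin loss on a small separable set", {
  sim <- simulate_pairs(50, seq_len = 30, noise_rate = 0, seed = 31)
  cfg <- caps_config(seq_len = 30, msc_filters = 8, gru_units = 8,
                     primary_caps_channels = 4, dropout_rate = 0, seed = 1)
  fit <- fit_capsnet(sim, cfg, train_config(batch_size = 16, max_epochs = 6,
                                            patience = 6,
                                            validation_fraction = 0.2,
                                            seed = 2))
  h <- tidy(fit)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_lte(fit$best_val_loss, min(h$val_loss))   # restored best <= observed
  g <- glance(fit)
  expect_equal(g$n_train + g$n_valid, 50L)
})

test_that("two runs with one seed are identical; different seeds diverge", {
  sim <- simulate_pairs(40, seq_len = 25, noise_rate = 0, seed = 32)
  cfg <- caps_config(seq_len = 25, msc_filters = 4, gru_units = 4,
                     primary_caps_channels = 2, seed = 1)
  tc <- train_config(batch_size = 20, max_epochs = 3, patience = 3, seed = 5,
                     validation_fraction = 0.2)
  f1 <- fit_capsnet(sim, cfg, tc)
  f2 <- fit_capsnet(sim, cfg, tc)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$params, f2$params)
  tc2 <- tc; tc2$seed <- 6L
  f3 <- fit_capsnet(sim, cfg, tc2)
  expect_false(identical(f1$history$train_loss, f3$history$train_loss))
})

test_that("training errors when a split would empty a class", {
  tbl <- random_pairs_tbl(6, 20, seed = 33)
  tbl$label <- c(1L, rep(0L, 5))                    # single positive
  cfg <- caps_config(seq_len = 20, msc_filters = 4, gru_units = 4,
                     primary_caps_channels = 2)
  expect_error(fit_capsnet(tbl, cfg, train_config(validation_fraction = 0.2)),
               "class|split")
})

test_that("a minimal k=2 cross-validation completes with disjoint folds", {
  sim <- simulate_pairs(40, seq_len = 25, noise_rate = 0, seed = 34)
  cfg <- caps_config(seq_len = 25, msc_filters = 4, gru_units = 4,
                     primary_caps_channels = 2, seed = 1)
  tc <- train_config(batch_size = 16, max_epochs = 2, patience = 2,
                     n_folds = 2, seed = 9, validation_fraction = 0.2)
  cv <- crossval_capsnet(sim, cfg, tc)
  expect_equal(nrow(cv$folds), 2L)
  expect_setequal(cv$fold_assignment, c(1L, 2L))
  expect_equal(sort(unlist(lapply(1:2, function(f) which(cv$fold_assignment == f)))),
               1:40)                                # partition of all indices
  expect_equal(nrow(cv$predictions), 40L)           # pooled out-of-fold
  g <- glance(cv)
  expect_true(all(c("mean_auc", "pooled_auc") %in% names(g)))
  # identical master seed reproduces the fold assignment
  cv2 <- crossval_capsnet(sim, cfg, tc)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(glance(cv), glance(cv2))
})
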