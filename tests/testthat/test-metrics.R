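# Confusion counts, scalar metrics, ROC/PR AUC oracles, evaluation plumbing.

test_that("confusion counts follow the standard 2x2 table", {
  c1 <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(c1), c(tp = 1, tn = 1, fp = 1, fn = 1))
  labels <- rep(c(1, 0), each = 5)
  c2 <- confusion_counts(labels, labels)
  expect_equal(c2$fp + c2$fn, 0)
  c3 <- confusion_counts(labels, rep(1, 10))
  expect_equal(unlist(c3), c(tp = 5, tn = 0, fp = 5, fn = 0))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "lengths differ")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
})

test_that("accuracy/precision/recall/F1 reproduce the worked case", {
  m <- classification_metrics(tibble::tibble(tp = 4, tn = 3, fp = 2, fn = 1))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 2 * (2 / 3) * 0.8 / ((2 / 3) + 0.8))  # 0.727272...
  expect_equal(m$f1, 0.727272727272727, tolerance = 1e-12)
  perfect <- classification_metrics(tibble::tibble(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
})

test_that("zero-denominator metrics are an explicit undefined marker", {
  m <- classification_metrics(tibble::tibble(tp = 0, tn = 5, fp = 0, fn = 3))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_equal(m$recall, 0)
  m2 <- classification_metrics(tibble::tibble(tp = 0, tn = 5, fp = 2, fn = 0))
  expect_true(is.na(m2$recall))     # no positives at all
  expect_error(classification_metrics(tibble::tibble(tp = 0, tn = 0, fp = 0, fn = 0)),
               "no samples")
})

test_that("ROC AUC: worked values and degenerate cases", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)   # all ties
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("ROC/PR AUC match brute-force enumeration on 200 random instances", {
  withr::with_seed(40, {
    for (rep in 1:200) {
      n <- sample(4:30, 1)
      truth <- c(1, 0, rbinom(n - 2, 1, 0.5))   # both classes guaranteed
      score <- if (rep %% 3 == 0) {
        sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
      } else {
        runif(n)
      }
      expect_equal(roc_auc(truth, score), oracle_auc(truth, score),
                   tolerance = 1e-12)
      expect_equal(pr_auc(truth, score), oracle_aupr(truth, score),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      n <- sample(6:30, 1)
      truth <- c(1, 0, rbinom(n - 2, 1, 0.5))
      score <- runif(n)
      base <- roc_auc(truth, score)
      expect_equal(roc_auc(truth, exp(3 * score)), base, tolerance = 1e-12)
      expect_equal(roc_auc(truth, rank(score)), base, tolerance = 1e-12)
      # complement symmetry (no ties here almost surely)
      expect_equal(roc_auc(1 - truth, score), 1 - base, tolerance = 1e-12)
    }
  })
})

test_that("PR AUC worked cases", {
  expect_equal(pr_auc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_error(pr_auc(c(0, 0), c(0.2, 0.3)), "positive")
})

test_that("metrics_report assembles consistent pieces", {
  withr::with_seed(42, {
    truth <- rbinom(40, 1, 0.5); truth[1:2] <- c(1, 0)
    score <- runif(40)
    est <- as.integer(score > 0.5)
    rep <- metrics_report(truth, score, est)
    expect_s3_class(rep, "loop_metrics")
    # accuracy == mean(pred == label) exactly
    expect_equal(rep$scalars$accuracy, mean(est == truth))
    expect_equal(rep$auc, oracle_auc(truth, score), tolerance = 1e-12)
    g <- glance(rep)
    expect_equal(g$n, 40)
    td <- tidy(rep)
    expect_true(all(c("accuracy", "auc", "aupr") %in% td$metric))
    # F1 consistency with stored precision/recall
    expect_equal(g$f1, 2 * g$precision * g$recall / (g$precision + g$recall))
  })
})

test_that("cross_cell_auc fills a labeled AUC matrix and checks inputs", {
  cfg <- tiny_config()
  m <- capsnet_init_model(cfg)
  fit <- structure(list(params = m$params, config = cfg, shapes = m$shapes),
                   class = c("capsnet_fit", "capsnet_model"))
  da <- random_pairs_tbl(12, 20, seed = 43)
  db <- random_pairs_tbl(12, 20, seed = 44)
  cc <- cross_cell_auc(list(A = fit, B = fit), list(A = da, B = db))
  expect_equal(nrow(cc), 4L)
  mat <- cross_cell_matrix(cc)
  expect_equal(dim(mat), c(2L, 2L))
  expect_equal(rownames(mat), c("A", "B"))
  # same model evaluated on the same data: symmetric rows
  expect_equal(mat["A", "A"], mat["B", "A"])
  expect_error(cross_cell_auc(list(A = fit), list(A = da)), "at least 2")
  expect_error(cross_cell_auc(list(A = fit, B = fit), list(A = da)),
               "missing evaluation dataset")
})

test_that("embedding export has the documented shape and is deterministic", {
  cfg <- tiny_config()
  m <- capsnet_init_model(cfg)
  fit <- structure(list(params = m$params, config = cfg, shapes = m$shapes),
                   class = c("capsnet_fit", "capsnet_model"))
  tbl <- random_pairs_tbl(10, 20, seed = 45)
  emb <- export_embeddings(fit, tbl, layer = "digit_caps")
  expect_equal(dim(emb), c(10L, 2L + 2L * 3L))   # id, label + J*D values
  emb2 <- export_embeddings(fit, tbl, layer = "digit_caps")
  expect_identical(emb, emb2)
  inp <- export_embeddings(NULL, tbl, layer = "input")
  expect_equal(dim(inp), c(10L, 2L + 2L * 20L * 4L))
  expect_error(export_embeddings(fit, tbl, layer = "bogus"))
})
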