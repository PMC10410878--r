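# Full forward pass: shape contracts, ablation pass-throughs, determinism,
# the decision rule, and the end-to-end gradient check.

test_that("config validation enforces the documented invariants", {
  expect_error(caps_config(seq_len = 5), "largest multi-scale kernel")
  expect_error(caps_config(dropout_rate = 1), "dropout_rate")
  expect_error(caps_config(m_plus = 0.1, m_minus = 0.9), "m_minus < m_plus")
  expect_error(caps_config(routing_iterations = 0), "positive")
  expect_error(caps_config(digit_caps_count = 3), "2 digit capsules")
})

test_that("forward pass emits batch x 2 x 8 digit capsules for L in {100, 506}", {
  for (L in c(100L, 506L)) {
    cfg <- caps_config(seq_len = L)
    m <- capsnet_init_model(cfg)
    withr::with_seed(20, {
      xa <- array(runif(2 * L * 4), c(2, L, 4))
      xb <- array(runif(2 * L * 4), c(2, L, 4))
    })
    fwd <- loopcaps:::capsnet_fwd(m$params, cfg, xa, xb)
    expect_equal(dim(fwd$v), c(2L, 16L))           # 2 capsules x 8 dims
    expect_equal(dim(fwd$lengths), c(2L, 2L))
    if (L == 506L) {
      # 506 -> 253 -> 127 per branch; merged 254 -> 127 positions x 16 channels
      expect_equal(fwd$n_primary, 2032L)
    }
  }
})

test_that("ablation switches keep the pipeline shape-compatible", {
  L <- 100L
  withr::with_seed(21, {
    xa <- array(runif(2 * L * 4), c(2, L, 4))
    xb <- array(runif(2 * L * 4), c(2, L, 4))
  })
  for (msc in c(TRUE, FALSE)) {
    for (bigru in c(TRUE, FALSE)) {
      cfg <- caps_config(seq_len = L, use_msc = msc, use_bigru = bigru)
      m <- capsnet_init_model(cfg)
      fwd <- loopcaps:::capsnet_fwd(m$params, cfg, xa, xb)
      expect_equal(dim(fwd$v), c(2L, 16L))
      expect_equal(dim(fwd$lengths), c(2L, 2L))
    }
  }
})

test_that("inference is deterministic and swapping branches changes features", {
  cfg <- tiny_config()
  m <- capsnet_init_model(cfg)
  withr::with_seed(22, {
    xa <- array(runif(3 * 20 * 4), c(3, 20, 4))
    xb <- array(runif(3 * 20 * 4), c(3, 20, 4))
  })
  f1 <- loopcaps:::capsnet_fwd(m$params, cfg, xa, xb)
  f2 <- loopcaps:::capsnet_fwd(m$params, cfg, xa, xb)
  expect_identical(f1$lengths, f2$lengths)         # bitwise-equal
  # merge order is a-then-b: swapping the anchors permutes the merged map
  fs <- loopcaps:::capsnet_fwd(m$params, cfg, xb, xa)
  expect_false(isTRUE(all.equal(f1$lengths, fs$lengths)))
})

test_that("capsule_decision uses argmax with ties to class 0 and loop score", {
  lengths <- matrix(c(0.1, 0.9,    # clear loop
                      0.9, 0.1,    # clear no-loop
                      0.4, 0.4),   # tie
                    3, 2, byrow = TRUE)
  dec <- capsule_decision(lengths)
  expect_equal(dec$class, c(1L, 0L, 0L))
  expect_equal(dec$score, lengths[, 2])            # always the loop capsule
})

test_that("backprop matches finite differences across every layer type", {
  cfg <- tiny_config()
  m <- capsnet_init_model(cfg)
  withr::with_seed(23, {
    xa <- array(runif(3 * 20 * 4), c(3, 20, 4))
    xb <- array(runif(3 * 20 * 4), c(3, 20, 4))
  })
  y <- c(1, 0, 1)
  r <- loopcaps:::capsnet_loss(m$params, cfg, xa, xb, y, with_grads = TRUE)
  fl <- loopcaps:::tree_flatten(m$params)
  gl <- loopcaps:::tree_flatten(r$grads)
  expect_identical(names(fl$leaves), names(gl$leaves))
  lossfn <- function(vals) {
    p <- loopcaps:::tree_unflatten(m$params, vals)
    loopcaps:::capsnet_loss(p, cfg, xa, xb, y, with_grads = FALSE)$loss
  }
  eps <- 1e-5
  withr::with_seed(24, idx <- sample(length(fl$values), 30))
  for (i in idx) {
    vp <- fl$values; vp[i] <- vp[i] + eps
    vm <- fl$values; vm[i] <- vm[i] - eps
    fd <- (lossfn(vp) - lossfn(vm)) / (2 * eps)
    an <- gl$values[i]
    expect_lt(abs(fd - an) / max(abs(fd) + abs(an), 1e-6), 1e-4)
  }
})

test_that("independent-weight branches are supported as a config flag", {
  cfg <- tiny_config(share_weights = FALSE)
  m <- capsnet_init_model(cfg)
  expect_true(all(c("enc_a", "enc_b") %in% names(m$params)))
  withr::with_seed(25, {
    xa <- array(runif(2 * 20 * 4), c(2, 20, 4))
    xb <- array(runif(2 * 20 * 4), c(2, 20, 4))
  })
  fwd <- loopcaps:::capsnet_fwd(m$params, cfg, xa, xb)
  expect_equal(dim(fwd$lengths), c(2L, 2L))
  # gradient check also holds without weight sharing
  y <- c(1, 0)
  r <- loopcaps:::capsnet_loss(m$params, cfg, xa, xb, y, with_grads = TRUE)
  fl <- loopcaps:::tree_flatten(m$params)
  gl <- loopcaps:::tree_flatten(r$grads)
  lossfn <- function(vals) {
    p <- loopcaps:::tree_unflatten(m$params, vals)
    loopcaps:::capsnet_loss(p, cfg, xa, xb, y, with_grads = FALSE)$loss
  }
  eps <- 1e-5
  withr::with_seed(26, idx <- sample(length(fl$values), 8))
  for (i in idx) {
    vp <- fl$values; vp[i] <- vp[i] + eps
    vm <- fl$values; vm[i] <- vm[i] - eps
    fd <- (lossfn(vp) - lossfn(vm)) / (2 * eps)
    expect_lt(abs(fd - gl$values[i]) / max(abs(fd) + abs(gl$values[i]), 1e-6),
              1e-4)
  }
})

test_that("checkpoints round-trip weights and configuration", {
  cfg <- tiny_config()
  m <- capsnet_init_model(cfg)
  fit <- structure(list(params = m$params, config = cfg, shapes = m$shapes),
                   class = c("capsnet_fit", "capsnet_model"))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_capsnet(fit, path)
  back <- load_capsnet(path)
  expect_identical(back$params, fit$params)
  expect_identical(back$config, fit$config)
  expect_error(load_capsnet(withr::local_tempfile(fileext = ".rds") |>
                              (\(p) { saveRDS(list(a = 1), p); p })()),
               "not a loopcaps checkpoint")
})
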