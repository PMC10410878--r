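# Independent reference implementations used as oracles. Everything here is
# deliberately scalar / brute-force and shares no code with the package
# internals it checks.

# Small model configuration used for fast structural and gradient tests.
tiny_config <- function(...) {
  caps_config(seq_len = 20, msc_kernel_sizes = c(3, 5), msc_filters = 3,
              gru_units = 3, primary_caps_channels = 2, primary_caps_dim = 3,
              primary_caps_kernel = 5, digit_caps_dim = 3, dropout_rate = 0,
              seed = 42, ...)
}

random_pairs_tbl <- function(n, L, seed = 1) {
  withr::with_seed(seed, {
    draw <- function() {
      vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, character(1))
    }
    tibble::tibble(id = sprintf("p%03d", seq_len(n)),
                   seq_a = draw(), seq_b = draw(),
                   label = rep_len(c(1L, 0L), n))
  })
}

# Brute-force 1-D convolution with "same" padding: scalar loops only.
oracle_conv1d <- function(x, W, b, stride, relu = TRUE) {
  B <- dim(x)[1]; T_in <- dim(x)[2]; C <- dim(x)[3]
  k <- dim(W)[1]; F_ <- dim(W)[3]
  t_out <- ceiling(T_in / stride)
  pad_total <- max((t_out - 1) * stride + k - T_in, 0)
  left <- pad_total %/% 2
  out <- array(0, dim = c(B, t_out, F_))
  for (bb in seq_len(B)) {
    for (t in seq_len(t_out)) {
      for (f in seq_len(F_)) {
        acc <- b[f]
        for (j in seq_len(k)) {
          pos <- (t - 1) * stride + j - left
          if (pos >= 1 && pos <= T_in) {
            for (c in seq_len(C)) acc <- acc + x[bb, pos, c] * W[j, c, f]
          }
        }
        out[bb, t, f] <- if (relu) max(acc, 0) else acc
      }
    }
  }
  out
}

# Scalar GRU recurrence (classical gating, matching the documented equations).
oracle_gru <- function(x, p) {
  B <- dim(x)[1]; T_in <- dim(x)[2]
  U <- ncol(p$Wz)
  H <- array(0, dim = c(B, T_in, U))
  sig <- function(v) 1 / (1 + exp(-v))
  for (bb in seq_len(B)) {
    h <- numeric(U)
    for (t in seq_len(T_in)) {
      xt <- x[bb, t, ]
      z <- sig(as.numeric(xt %*% p$Wz) + as.numeric(h %*% p$Uz) + p$bz)
      r <- sig(as.numeric(xt %*% p$Wr) + as.numeric(h %*% p$Ur) + p$br)
      g <- tanh(as.numeric(xt %*% p$Wh) + as.numeric((r * h) %*% p$Uh) + p$bh)
      h <- z * h + (1 - z) * g
      H[bb, t, ] <- h
    }
  }
  H
}

# Shares the documented epsilon guard (1e-8 inside the square root) so the
# vectorized implementation can be held to 1e-10.
oracle_squash <- function(s) {
  n2 <- sum(s^2)
  (n2 / (1 + n2)) * s / sqrt(n2 + 1e-8)
}

# Scalar routing-by-agreement: uhat (B, N, J*D) with D-blocks per output
# capsule; logits start at zero, softmax over output capsules.
oracle_routing <- function(uhat, J, D, iterations) {
  B <- dim(uhat)[1]; N <- dim(uhat)[2]
  v_all <- array(0, dim = c(B, J, D))
  for (bb in seq_len(B)) {
    u <- array(0, dim = c(N, J, D))
    for (i in seq_len(N)) {
      for (j in seq_len(J)) u[i, j, ] <- uhat[bb, i, (j - 1) * D + seq_len(D)]
    }
    b_log <- matrix(0, N, J)
    v <- matrix(0, J, D)
    for (r in seq_len(iterations)) {
      cc <- t(apply(b_log, 1, function(row) exp(row - max(row)) /
                      sum(exp(row - max(row)))))
      for (j in seq_len(J)) {
        s <- numeric(D)
        for (i in seq_len(N)) s <- s + cc[i, j] * u[i, j, ]
        v[j, ] <- oracle_squash(s)
      }
      if (r < iterations) {
        for (i in seq_len(N)) {
          for (j in seq_len(J)) b_log[i, j] <- b_log[i, j] + sum(u[i, j, ] * v[j, ])
        }
      }
    }
    v_all[bb, , ] <- v
  }
  v_all
}

# Pairwise-enumeration ROC AUC (wins + half-ties over all pos x neg pairs).
oracle_auc <- function(truth, score) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Threshold-sweep PR AUC with step-wise accumulation.
oracle_aupr <- function(truth, score) {
  ths <- sort(unique(score), decreasing = TRUE)
  n_pos <- sum(truth == 1)
  area <- 0; prev_recall <- 0
  for (th in ths) {
    sel <- score >= th
    tp <- sum(truth == 1 & sel); fp <- sum(truth == 0 & sel)
    recall <- tp / n_pos
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}
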