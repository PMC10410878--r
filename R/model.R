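# Model assembly: configuration, weight initialization, and the full
# forward/backward computation
#   per-branch [multi-scale conv -> fusion conv -> Bi-GRU] (weight-shared)
#   -> position-axis merge -> primary capsules -> dynamic routing
#   -> digit-capsule lengths -> margin loss.

#' Model configuration
#'
#' Collects every architecture hyperparameter. Defaults are the optimized
#' values of the published model: multi-scale kernels 3/5/7 with 32 filters
#' and stride 2, fusion kernel 5 with 32 filters and stride 2, 32 GRU units
#' per direction, 16 primary-capsule channels of dimension 8 (kernel 9,
#' stride 2), two 8-dimensional digit capsules, 3 routing iterations,
#' dropout 0.5, and margin-loss constants 0.9/0.1/0.5.
#'
#' @param seq_len Input sequence length `L` (506 for the YY1 benchmark); all
#'   downstream shapes are derived from it.
#' @param msc_kernel_sizes Kernel sizes of the parallel multi-scale
#'   convolutions.
#' @param msc_filters,msc_stride Filters and stride shared by the multi-scale
#'   convolutions.
#' @param fusion_kernel,fusion_filters,fusion_stride The fusion convolution.
#' @param gru_units GRU units per direction (output is `2 * gru_units`).
#' @param primary_caps_channels,primary_caps_dim,primary_caps_kernel,primary_caps_stride
#'   The primary (convolutional) capsule layer.
#' @param digit_caps_count,digit_caps_dim Digit capsules; the loop task uses
#'   exactly 2 capsules (no-loop, loop).
#' @param routing_iterations Dynamic-routing rounds (>= 1).
#' @param dropout_rate Dropout applied to the encoder output during training.
#' @param m_plus,m_minus,lambda Margin-loss constants.
#' @param use_msc,use_bigru Ablation switches; a disabled stage becomes an
#'   identity pass-through.
#' @param share_weights If `TRUE` (default) both anchors pass through one
#'   weight-shared encoder; `FALSE` gives each branch its own weights.
#' @param seed Seed for weight initialization.
#' @return A list of class `caps_config`.
#' @export
caps_config <- function(seq_len = 506L,
                        msc_kernel_sizes = c(3L, 5L, 7L),
                        msc_filters = 32L, msc_stride = 2L,
                        fusion_kernel = 5L, fusion_filters = 32L,
                        fusion_stride = 2L,
                        gru_units = 32L,
                        primary_caps_channels = 16L, primary_caps_dim = 8L,
                        primary_caps_kernel = 9L, primary_caps_stride = 2L,
                        digit_caps_count = 2L, digit_caps_dim = 8L,
                        routing_iterations = 3L,
                        dropout_rate = 0.5,
                        m_plus = 0.9, m_minus = 0.1, lambda = 0.5,
                        use_msc = TRUE, use_bigru = TRUE,
                        share_weights = TRUE,
                        seed = 1L) {
  cfg <- list(seq_len = as.integer(seq_len),
              msc_kernel_sizes = as.integer(msc_kernel_sizes),
              msc_filters = as.integer(msc_filters),
              msc_stride = as.integer(msc_stride),
              fusion_kernel = as.integer(fusion_kernel),
              fusion_filters = as.integer(fusion_filters),
              fusion_stride = as.integer(fusion_stride),
              gru_units = as.integer(gru_units),
              primary_caps_channels = as.integer(primary_caps_channels),
              primary_caps_dim = as.integer(primary_caps_dim),
              primary_caps_kernel = as.integer(primary_caps_kernel),
              primary_caps_stride = as.integer(primary_caps_stride),
              digit_caps_count = as.integer(digit_caps_count),
              digit_caps_dim = as.integer(digit_caps_dim),
              routing_iterations = as.integer(routing_iterations),
              dropout_rate = dropout_rate,
              m_plus = m_plus, m_minus = m_minus, lambda = lambda,
              use_msc = isTRUE(use_msc), use_bigru = isTRUE(use_bigru),
              share_weights = isTRUE(share_weights),
              seed = as.integer(seed))
  sizes <- c(cfg$seq_len, cfg$msc_kernel_sizes, cfg$msc_filters,
             cfg$msc_stride, cfg$fusion_kernel, cfg$fusion_filters,
             cfg$fusion_stride, cfg$gru_units, cfg$primary_caps_channels,
             cfg$primary_caps_dim, cfg$primary_caps_kernel,
             cfg$primary_caps_stride, cfg$digit_caps_count,
             cfg$digit_caps_dim, cfg$routing_iterations)
  if (any(sizes < 1L)) stop("all size parameters must be positive integers",
                            call. = FALSE)
  if (cfg$digit_caps_count != 2L) {
    stop("the loop/no-loop task uses exactly 2 digit capsules", call. = FALSE)
  }
  if (!(dropout_rate >= 0 && dropout_rate < 1)) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (!(m_minus > 0 && m_minus < m_plus && m_plus < 1)) {
    stop("need 0 < m_minus < m_plus < 1", call. = FALSE)
  }
  if (cfg$use_msc && cfg$seq_len < max(cfg$msc_kernel_sizes)) {
    stop("seq_len is smaller than the largest multi-scale kernel",
         call. = FALSE)
  }
  shp <- caps_shapes(cfg)
  if (2L * shp$t_enc < cfg$primary_caps_kernel) {
    stop("merged feature map is shorter than the primary-capsule kernel",
         call. = FALSE)
  }
  structure(cfg, class = "caps_config")
}

# Shape chain derived from L (rather than hard-coded for 506).
caps_shapes <- function(cfg) {
  L <- cfg$seq_len
  if (cfg$use_msc) {
    t1 <- ceiling(L / cfg$msc_stride)
    c1 <- length(cfg$msc_kernel_sizes) * cfg$msc_filters
  } else {
    t1 <- L; c1 <- 4L
  }
  t2 <- ceiling(t1 / cfg$fusion_stride)
  c2 <- cfg$fusion_filters
  c_enc <- if (cfg$use_bigru) 2L * cfg$gru_units else c2
  t_merged <- 2L * t2
  p_pos <- ceiling(t_merged / cfg$primary_caps_stride)
  n_primary <- p_pos * cfg$primary_caps_channels
  list(t_msc = as.integer(t1), c_msc = as.integer(c1),
       t_enc = as.integer(t2), c_enc = as.integer(c_enc),
       t_merged = as.integer(t_merged), p_pos = as.integer(p_pos),
       n_primary = as.integer(n_primary))
}

encoder_init <- function(cfg, rng) {
  shp <- caps_shapes(cfg)
  enc <- list()
  if (cfg$use_msc) {
    enc$msc <- lapply(cfg$msc_kernel_sizes, function(k) {
      conv1d_init(k, 4L, cfg$msc_filters, rng)
    })
  }
  enc$fus <- conv1d_init(cfg$fusion_kernel, shp$c_msc, cfg$fusion_filters, rng)
  if (cfg$use_bigru) {
    enc$gru <- bigru_init(cfg$fusion_filters, cfg$gru_units, rng)
  }
  enc
}

#' Initialize an untrained capsule-network model
#'
#' Builds the full weight set for a [caps_config()] with variance-scaling
#' (Glorot-uniform) initialization seeded from `config$seed`. Useful for
#' inspecting shapes and for testing; training is done by [fit_capsnet()].
#'
#' @param config A [caps_config()].
#' @return An object of class `capsnet_model` holding `params`, `config`,
#'   and the derived shape table.
#' @export
capsnet_init_model <- function(config) {
  stopifnot(inherits(config, "caps_config"))
  shp <- caps_shapes(config)
  params <- withr::with_seed(config$seed, {
    rng <- function(n, limit) stats::runif(n, -limit, limit)
    p <- list()
    if (config$share_weights) {
      p$enc <- encoder_init(config, rng)
    } else {
      p$enc_a <- encoder_init(config, rng)
      p$enc_b <- encoder_init(config, rng)
    }
    p$caps <- conv1d_init(config$primary_caps_kernel, shp$c_enc,
                          config$primary_caps_channels * config$primary_caps_dim,
                          rng)
    pd <- config$primary_caps_dim
    jd <- config$digit_caps_count * config$digit_caps_dim
    limit <- sqrt(6 / (pd + jd))
    p$route <- array(rng(pd * jd * shp$n_primary, limit),
                     dim = c(pd, jd, shp$n_primary))
    p
  })
  structure(list(params = params, config = config, shapes = shp),
            class = "capsnet_model")
}

#' @export
print.capsnet_model <- function(x, ...) {
  cat(sprintf("<%s> L = %d, %d primary capsules (dim %d) -> %d digit capsules (dim %d)\n",
              class(x)[1L], x$config$seq_len, x$shapes$n_primary,
              x$config$primary_caps_dim, x$config$digit_caps_count,
              x$config$digit_caps_dim))
  cat(sprintf("  use_msc = %s, use_bigru = %s, %d parameters\n",
              x$config$use_msc, x$config$use_bigru,
              length(tree_flatten(x$params)$values)))
  invisible(x)
}

# ---- encoder (one branch or the stacked pair) -----------------------------

encoder_fwd <- function(x, ep, cfg, training) {
  cache <- list()
  if (cfg$use_msc) {
    convs <- lapply(seq_along(cfg$msc_kernel_sizes), function(i) {
      conv1d_fwd(x, ep$msc[[i]]$W, ep$msc[[i]]$b, cfg$msc_stride, "relu")
    })
    h <- array(0, dim = c(dim(x)[1L], dim(convs[[1L]]$out)[2L],
                          length(convs) * cfg$msc_filters))
    for (i in seq_along(convs)) {
      h[, , (i - 1L) * cfg$msc_filters + seq_len(cfg$msc_filters)] <-
        convs[[i]]$out
    }
    cache$msc <- lapply(convs, `[[`, "cache")
  } else {
    h <- x
  }
  fus <- conv1d_fwd(h, ep$fus$W, ep$fus$b, cfg$fusion_stride, "relu")
  cache$fus <- fus$cache
  h <- fus$out
  if (cfg$use_bigru) {
    gru <- bigru_fwd(h, ep$gru)
    cache$gru <- gru$cache
    h <- gru$out
  }
  dr <- dropout_fwd(h, cfg$dropout_rate, training)
  cache$drop_mask <- dr$mask
  list(out = dr$out, cache = cache)
}

encoder_bwd <- function(dout, cache, ep, cfg) {
  grads <- list()
  dh <- dropout_bwd(dout, cache$drop_mask)
  if (cfg$use_bigru) {
    g <- bigru_bwd(dh, cache$gru, ep$gru)
    grads$gru <- g$grads
    dh <- g$dx
  }
  f <- conv1d_bwd(dh, cache$fus, ep$fus$W)
  grads$fus <- list(W = f$dW, b = f$db)
  dh <- f$dx
  if (cfg$use_msc) {
    dx <- NULL
    grads$msc <- vector("list", length(cfg$msc_kernel_sizes))
    for (i in seq_along(cfg$msc_kernel_sizes)) {
      cols <- (i - 1L) * cfg$msc_filters + seq_len(cfg$msc_filters)
      gi <- conv1d_bwd(dh[, , cols, drop = FALSE], cache$msc[[i]],
                       ep$msc[[i]]$W)
      grads$msc[[i]] <- list(W = gi$dW, b = gi$db)
      dx <- if (is.null(dx)) gi$dx else dx + gi$dx
    }
    dh <- dx
  }
  list(dx = dh, grads = grads)
}

# ---- full forward ---------------------------------------------------------

# x_a, x_b: (B, L, 4). Returns digit-capsule vectors, lengths, primary
# capsules, coupling coefficients, and (if keep_cache) everything needed for
# the backward pass.
capsnet_fwd <- function(params, cfg, x_a, x_b, training = FALSE,
                        keep_cache = FALSE, debug_routing = FALSE) {
  B <- dim(x_a)[1L]
  stopifnot(identical(dim(x_a), dim(x_b)), dim(x_a)[2L] == cfg$seq_len)
  shp <- caps_shapes(cfg)
  if (cfg$share_weights) {
    xs <- array(0, dim = c(2L * B, cfg$seq_len, 4L))
    xs[seq_len(B), , ] <- x_a
    xs[B + seq_len(B), , ] <- x_b
    enc <- encoder_fwd(xs, params$enc, cfg, training)
    out_a <- enc$out[seq_len(B), , , drop = FALSE]
    out_b <- enc$out[B + seq_len(B), , , drop = FALSE]
    enc_cache <- list(shared = enc$cache)
  } else {
    enc_a <- encoder_fwd(x_a, params$enc_a, cfg, training)
    enc_b <- encoder_fwd(x_b, params$enc_b, cfg, training)
    out_a <- enc_a$out; out_b <- enc_b$out
    enc_cache <- list(a = enc_a$cache, b = enc_b$cache)
  }
  T_ <- dim(out_a)[2L]; C_ <- dim(out_a)[3L]
  merged <- array(0, dim = c(B, 2L * T_, C_))
  merged[, seq_len(T_), ] <- out_a
  merged[, T_ + seq_len(T_), ] <- out_b
  # primary capsules: linear conv then per-capsule squash
  pc <- conv1d_fwd(merged, params$caps$W, params$caps$b,
                   cfg$primary_caps_stride, "linear")
  pd <- cfg$primary_caps_dim; ch <- cfg$primary_caps_channels
  P <- dim(pc$out)[2L]
  y4 <- array(pc$out, dim = c(B, P, pd, ch))
  u_raw <- aperm(y4, c(1L, 4L, 2L, 3L))          # (B, ch, P, pd)
  dim(u_raw) <- c(B, ch * P, pd)                 # capsule i = (p-1)*ch + c
  N <- ch * P
  um <- u_raw
  dim(um) <- c(B * N, pd)
  usq <- squash_fwd(um)
  u <- array(usq$out, dim = c(B, N, pd))
  # learned transforms to digit-capsule prediction vectors:
  # uhat[b,i,cc] = sum_e u[b,i,e] * route[e,cc,i], vectorized over (b,i)
  jd <- cfg$digit_caps_count * cfg$digit_caps_dim
  uflat <- usq$out                               # (B*N, pd), row = (b, i)
  uhat <- caps_transform_fwd_cpp(uflat, params$route, B)
  dim(uhat) <- c(B, N, jd)
  rt <- routing_fwd(uhat, cfg$digit_caps_count, cfg$digit_caps_dim,
                    cfg$routing_iterations, debug = debug_routing)
  res <- list(v = rt$v, lengths = rt$lengths, primary = u,
              coupling = rt$coupling, n_primary = N)
  if (keep_cache) {
    res$cache <- list(enc = enc_cache, pc = pc$cache, usq = usq$cache,
                      uflat = uflat, rt = rt$cache,
                      B = B, T_ = T_, C_ = C_, P = P, pd = pd, ch = ch, N = N)
  }
  res
}

# Backward pass from the gradient w.r.t. digit-capsule lengths.
capsnet_bwd <- function(dlengths, fwd, params, cfg) {
  cache <- fwd$cache
  B <- cache$B; N <- cache$N; pd <- cache$pd; ch <- cache$ch
  D <- cfg$digit_caps_dim; J <- cfg$digit_caps_count
  # d total / d v from lengths = ||v_j||
  dv <- matrix(0, B, J * D)
  for (j in seq_len(J)) {
    cols <- (j - 1L) * D + seq_len(D)
    lj <- pmax(fwd$lengths[, j], 1e-8)
    dv[, cols] <- fwd$v[, cols, drop = FALSE] * (dlengths[, j] / lj)
  }
  dU <- routing_bwd(dv, cache$rt)          # list of J*D (B,N) matrices
  jd <- length(dU)
  duhat <- matrix(0, B * N, jd)
  for (cc in seq_len(jd)) {
    dcc <- dU[[cc]]
    dim(dcc) <- NULL
    duhat[, cc] <- dcc
  }
  tb <- caps_transform_bwd_cpp(cache$uflat, duhat, params$route, B)
  droute <- tb$droute
  du_raw <- squash_bwd(tb$du, cache$usq)
  # undo the capsule reshape back to conv output layout
  P <- cache$P
  du4 <- array(du_raw, dim = c(B, ch, P, pd))
  dy4 <- aperm(du4, c(1L, 3L, 4L, 2L))           # (B, P, pd, ch)
  dy <- array(dy4, dim = c(B, P, pd * ch))
  pcb <- conv1d_bwd(dy, cache$pc, params$caps$W)
  grads <- list(caps = list(W = pcb$dW, b = pcb$db), route = droute)
  T_ <- cache$T_
  dmerged <- pcb$dx
  dout_a <- dmerged[, seq_len(T_), , drop = FALSE]
  dout_b <- dmerged[, T_ + seq_len(T_), , drop = FALSE]
  if (cfg$share_weights) {
    dstack <- array(0, dim = c(2L * B, T_, cache$C_))
    dstack[seq_len(B), , ] <- dout_a
    dstack[B + seq_len(B), , ] <- dout_b
    eb <- encoder_bwd(dstack, cache$enc$shared, params$enc, cfg)
    grads$enc <- eb$grads
  } else {
    eb_a <- encoder_bwd(dout_a, cache$enc$a, params$enc_a, cfg)
    eb_b <- encoder_bwd(dout_b, cache$enc$b, params$enc_b, cfg)
    grads$enc_a <- eb_a$grads
    grads$enc_b <- eb_b$grads
  }
  grads
}

# Loss + gradients for one batch; the entry point used by the optimizer and
# by finite-difference tests.
capsnet_loss <- function(params, cfg, x_a, x_b, labels, training = FALSE,
                         with_grads = TRUE) {
  fwd <- capsnet_fwd(params, cfg, x_a, x_b, training = training,
                     keep_cache = with_grads)
  ml <- margin_loss(fwd$lengths, labels, cfg$m_plus, cfg$m_minus, cfg$lambda)
  out <- list(loss = ml$total, lengths = fwd$lengths)
  if (with_grads) {
    out$grads <- tree_align(params, capsnet_bwd(ml$dlengths, fwd, params, cfg))
  }
  out
}

#' Classify from digit-capsule lengths
#'
#' The predicted class is the digit capsule with the larger length (ties
#' break toward class 0); the ranking score used for ROC/PR curves is the
#' positive (loop) capsule's length, regardless of the predicted class.
#'
#' @param lengths A `batch x 2` matrix of capsule lengths (column 1 =
#'   no-loop capsule, column 2 = loop capsule).
#' @return A tibble with columns `score` and `class`.
#' @export
capsule_decision <- function(lengths) {
  lengths <- as.matrix(lengths)
  stopifnot(ncol(lengths) == 2L)
  tibble::tibble(
    score = lengths[, 2L],
    class = as.integer(lengths[, 2L] > lengths[, 1L])
  )
}

# ---- parameter-tree utilities --------------------------------------------

# Pairs leaves by name where names exist (gradient trees may be assembled in
# a different order than the parameter tree).
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    nm <- names(a)
    out <- vector("list", length(a))
    names(out) <- nm
    for (i in seq_along(a)) {
      bi <- if (!is.null(nm) && nzchar(nm[i])) b[[nm[i]]] else b[[i]]
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    out
  } else {
    f(a, b)
  }
}

# Reorder `tree` to the shape/order of `template` (names where available).
tree_align <- function(template, tree) {
  if (!is.list(template)) return(tree)
  nm <- names(template)
  out <- vector("list", length(template))
  names(out) <- nm
  for (i in seq_along(template)) {
    ti <- if (!is.null(nm) && nzchar(nm[i])) tree[[nm[i]]] else tree[[i]]
    out[[i]] <- tree_align(template[[i]], ti)
  }
  out
}

tree_flatten <- function(tree) {
  leaves <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (i in seq_along(x)) {
        walk(x[[i]], c(path, if (is.null(names(x)[i]) || names(x)[i] == "")
          as.character(i) else names(x)[i]))
      }
    } else {
      leaves[[paste(path, collapse = "/")]] <<- x
    }
  }
  walk(tree, character())
  list(values = unlist(leaves, use.names = FALSE), leaves = leaves)
}

tree_unflatten <- function(tree, values) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) {
      for (i in seq_along(x)) x[[i]] <- walk(x[[i]])
      x
    } else {
      n <- length(x)
      out <- x
      out[] <- values[pos + seq_len(n)]
      pos <<- pos + n
      out
    }
  }
  walk(tree)
}
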