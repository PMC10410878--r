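# Capsule primitives: squash nonlinearity, dynamic routing-by-agreement,
# and the margin loss on digit-capsule lengths.

.squash_eps <- 1e-8

#' Squash a capsule vector
#'
#' The capsule nonlinearity `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`:
#' direction is preserved and the output norm is `||s||^2 / (1 + ||s||^2)`,
#' strictly inside `[0, 1)`. A small epsilon inside the square root guards
#' the zero vector, whose image is exactly zero.
#'
#' @param s A numeric vector, or a matrix whose rows are squashed
#'   independently.
#' @return An object of the same shape as `s`.
#' @examples
#' squash(c(0, 0))            # zero fixed point
#' sqrt(sum(squash(c(1, 0))^2))  # norm 1 -> 0.5
#' sqrt(sum(squash(c(3, 0))^2))  # norm 3 -> 0.9
#' @export
squash <- function(s) {
  if (is.null(dim(s))) return(drop(squash_fwd(matrix(s, nrow = 1L))$out))
  squash_fwd(s)$out
}

# Row-wise squash with cache for the backward pass.
squash_fwd <- function(S) {
  ss <- rowSums(S^2)
  q <- sqrt(ss + .squash_eps)
  coef <- ss / ((1 + ss) * q)
  list(out = S * coef, cache = list(S = S, ss = ss, q = q, coef = coef))
}

squash_bwd <- function(dV, cache) {
  ss <- cache$ss; q <- cache$q
  # d coef / d ss, from coef = ss / ((1+ss) q), q = sqrt(ss + eps)
  dcoef_dss <- (q - ss * (1 + ss) / (2 * q)) / ((1 + ss)^2 * q^2)
  proj <- rowSums(dV * cache$S)
  dV * cache$coef + cache$S * (2 * dcoef_dss * proj)
}

# ---- dynamic routing ------------------------------------------------------
# uhat: (B, N, J*D) prediction vectors, column block j holds dims
# (j-1)*D + 1 .. j*D. Routing logits b start at zero each forward pass and
# gradients flow through every iteration (no stop-gradient).

# Internally the prediction vectors are carried as a list of J*D matrices of
# shape (B, N) — one per (output capsule j, dimension d) — which avoids
# repeated 3-D array slicing in the routing loops.
uhat_to_cols <- function(uhat) {
  d <- dim(uhat); B <- d[1L]; N <- d[2L]
  lapply(seq_len(d[3L]), function(cc) {
    m <- uhat[, , cc, drop = FALSE]
    dim(m) <- c(B, N)
    m
  })
}

routing_fwd <- function(uhat, n_out, dim_out, iterations, debug = FALSE) {
  d <- dim(uhat); B <- d[1L]; N <- d[2L]
  stopifnot(d[3L] == n_out * dim_out, iterations >= 1L)
  J <- n_out; D <- dim_out
  U <- uhat_to_cols(uhat)
  b <- lapply(seq_len(J), function(j) matrix(0, B, N))
  iters <- vector("list", iterations)
  clist <- NULL; v <- NULL
  for (r in seq_len(iterations)) {
    bmax <- b[[1L]]
    for (j in seq_len(J)) bmax <- pmax(bmax, b[[j]])
    e <- lapply(seq_len(J), function(j) exp(b[[j]] - bmax))
    denom <- e[[1L]]
    for (j in seq.int(2L, J)) denom <- denom + e[[j]]
    clist <- lapply(seq_len(J), function(j) e[[j]] / denom)
    if (debug) {
      csum <- clist[[1L]]
      for (j in seq.int(2L, J)) csum <- csum + clist[[j]]
      stopifnot(max(abs(csum - 1)) < 1e-12)
    }
    s <- matrix(0, B, J * D)
    for (j in seq_len(J)) {
      cj <- clist[[j]]
      for (dd in seq_len(D)) {
        col <- (j - 1L) * D + dd
        s[, col] <- .rowSums(cj * U[[col]], B, N)
      }
    }
    sq <- lapply(seq_len(J), function(j) {
      squash_fwd(s[, (j - 1L) * D + seq_len(D), drop = FALSE])
    })
    v <- do.call(cbind, lapply(sq, `[[`, "out"))
    iters[[r]] <- list(c = clist, sq = sq, v = v)
    if (r < iterations) {
      for (j in seq_len(J)) {
        agree <- matrix(0, B, N)
        for (dd in seq_len(D)) {
          col <- (j - 1L) * D + dd
          agree <- agree + U[[col]] * v[, col]
        }
        b[[j]] <- b[[j]] + agree
      }
    }
  }
  lengths <- vapply(seq_len(J), function(j) {
    sqrt(rowSums(matrix(v[, (j - 1L) * D + seq_len(D)], nrow = B)^2))
  }, numeric(B))
  lengths <- matrix(lengths, nrow = B)
  coupling <- array(0, dim = c(B, N, J))
  for (j in seq_len(J)) coupling[, , j] <- clist[[j]]
  list(v = v, lengths = lengths, coupling = coupling,
       cache = list(iters = iters, B = B, N = N, J = J, D = D,
                    iterations = iterations, U = U))
}

# Backward through the unrolled routing loop; dv is the gradient w.r.t. the
# final digit-capsule matrix v (B, J*D). Returns the gradient w.r.t. uhat in
# the same column-list layout.
routing_bwd <- function(dv, cache) {
  B <- cache$B; N <- cache$N; J <- cache$J; D <- cache$D
  R <- cache$iterations
  U <- cache$U
  dU <- lapply(seq_len(J * D), function(cc) matrix(0, B, N))
  Gb <- NULL  # gradient w.r.t. b entering iteration r (i.e. b^{r})
  for (r in rev(seq_len(R))) {
    it <- cache$iters[[r]]
    if (r < R) {
      # b^{r} = b^{r-1} + sum_d uhat * v^{r}; Gb holds d/db^{r}
      dv_r <- matrix(0, B, J * D)
      for (j in seq_len(J)) {
        gj <- Gb[[j]]
        for (dd in seq_len(D)) {
          col <- (j - 1L) * D + dd
          dU[[col]] <- dU[[col]] + gj * it$v[, col]
          dv_r[, col] <- .rowSums(gj * U[[col]], B, N)
        }
      }
    } else {
      dv_r <- dv
      Gb <- lapply(seq_len(J), function(j) matrix(0, B, N))
    }
    # v^r = squash(s^r) per output capsule
    ds <- matrix(0, B, J * D)
    for (j in seq_len(J)) {
      cols <- (j - 1L) * D + seq_len(D)
      ds[, cols] <- squash_bwd(dv_r[, cols, drop = FALSE], it$sq[[j]]$cache)
    }
    # s^r = sum_i c^r uhat
    dc <- vector("list", J)
    for (j in seq_len(J)) {
      cj <- it$c[[j]]
      acc <- matrix(0, B, N)
      for (dd in seq_len(D)) {
        col <- (j - 1L) * D + dd
        dU[[col]] <- dU[[col]] + cj * ds[, col]
        acc <- acc + U[[col]] * ds[, col]
      }
      dc[[j]] <- acc
    }
    # c^r = softmax_j(b^{r-1}): db = c * (dc - sum_j c*dc)
    inner <- it$c[[1L]] * dc[[1L]]
    for (j in seq.int(2L, J)) inner <- inner + it$c[[j]] * dc[[j]]
    Gb_prev <- lapply(seq_len(J), function(j) it$c[[j]] * (dc[[j]] - inner))
    if (r < R) {
      # pass-through of b^{r} = b^{r-1} + ...
      for (j in seq_len(J)) Gb_prev[[j]] <- Gb_prev[[j]] + Gb[[j]]
    }
    Gb <- Gb_prev
  }
  # b^0 is the zero constant; Gb is discarded.
  dU
}

# ---- margin loss ----------------------------------------------------------

#' Margin loss on digit-capsule lengths
#'
#' Per class k: `L_k = T_k max(0, m_plus - ||v_k||)^2 +
#' lambda (1 - T_k) max(0, ||v_k|| - m_minus)^2`, with one-hot targets `T_k`;
#' the total is the batch mean of `sum_k L_k`. Defaults `m_plus = 0.9`,
#' `m_minus = 0.1`, `lambda = 0.5`.
#'
#' @param lengths A `batch x 2` matrix of capsule lengths; column 1 is the
#'   no-loop capsule (class 0), column 2 the loop capsule (class 1).
#' @param labels Binary vector of true classes.
#' @param m_plus,m_minus,lambda Margin-loss constants.
#' @return A list with `total` (scalar), `per_class` (`batch x 2` matrix of
#'   `L_k`), `targets` (one-hot `T_k`), and `dlengths` (gradient of `total`
#'   w.r.t. `lengths`).
#' @export
margin_loss <- function(lengths, labels, m_plus = 0.9, m_minus = 0.1,
                        lambda = 0.5) {
  lengths <- as.matrix(lengths)
  B <- nrow(lengths)
  stopifnot(ncol(lengths) == 2L, length(labels) == B,
            all(labels %in% c(0, 1)))
  T_k <- cbind(1 - labels, labels, deparse.level = 0)
  pos <- pmax(0, m_plus - lengths)
  neg <- pmax(0, lengths - m_minus)
  per_class <- T_k * pos^2 + lambda * (1 - T_k) * neg^2
  total <- sum(per_class) / B
  dlengths <- (-2 * T_k * pos + 2 * lambda * (1 - T_k) * neg) / B
  list(total = total, per_class = per_class, targets = T_k,
       dlengths = dlengths)
}
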