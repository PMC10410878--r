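# Gated recurrent unit, run bidirectionally over the time axis of a
# (batch, time, channels) feature map. The recurrence itself is compiled
# (see src/); these wrappers own initialization and the bidirectional
# plumbing.
#
# Gating follows the classical formulation (update gate z, reset gate r,
# reset applied to the previous state inside the candidate):
#   z_t = sigmoid(x_t Wz + h_{t-1} Uz + bz)
#   r_t = sigmoid(x_t Wr + h_{t-1} Ur + br)
#   g_t = tanh(x_t Wh + (r_t * h_{t-1}) Uh + bh)
#   h_t = z_t * h_{t-1} + (1 - z_t) * g_t
# so a zero input with zero biases has the zero state as fixed point.

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_init <- function(c_in, units, rng) {
  g <- function(nr, nc) {
    limit <- sqrt(6 / (nr + nc))
    matrix(rng(nr * nc, limit), nr, nc)
  }
  list(Wz = g(c_in, units), Wr = g(c_in, units), Wh = g(c_in, units),
       Uz = g(units, units), Ur = g(units, units), Uh = g(units, units),
       bz = numeric(units), br = numeric(units), bh = numeric(units))
}

# Forward over time; x (B,T,C) -> H (B,T,units) of per-step states. The
# compiled kernel keeps its caches time-major ((B, units, T) cubes).
gru_fwd <- function(x, p) {
  r <- gru_fwd_cpp(x, p$Wz, p$Wr, p$Wh, p$Uz, p$Ur, p$Uh, p$bz, p$br, p$bh)
  list(out = aperm(r$H, c(1L, 3L, 2L)),
       cache = list(x = x, H = r$H, Z = r$Z, R = r$R, G = r$G))
}

# Backward through time; dH (B,T,units) -> dx plus parameter gradients.
gru_bwd <- function(dH, cache, p) {
  g <- gru_bwd_cpp(cache$x, aperm(dH, c(1L, 3L, 2L)), cache$H, cache$Z,
                   cache$R, cache$G,
                   p$Wz, p$Wr, p$Wh, p$Uz, p$Ur, p$Uh)
  list(dx = g$dx,
       grads = list(Wz = g$Wz, Wr = g$Wr, Wh = g$Wh,
                    Uz = g$Uz, Ur = g$Ur, Uh = g$Uh,
                    bz = as.numeric(g$bz), br = as.numeric(g$br),
                    bh = as.numeric(g$bh)))
}

bigru_init <- function(c_in, units, rng) {
  list(fwd = gru_init(c_in, units, rng), bwd = gru_init(c_in, units, rng))
}

# Bidirectional GRU: one pass over time and a second over the reversed
# sequence; per-step outputs concatenated channel-wise (forward half first),
# the backward half re-aligned to the original time order.
bigru_fwd <- function(x, p) {
  T_ <- dim(x)[2L]
  f <- gru_fwd(x, p$fwd)
  xr <- x[, rev(seq_len(T_)), , drop = FALSE]
  b <- gru_fwd(xr, p$bwd)
  units <- ncol(p$fwd$Wz)
  out <- array(0, dim = c(dim(x)[1L], T_, 2L * units))
  out[, , seq_len(units)] <- f$out
  out[, , units + seq_len(units)] <- b$out[, rev(seq_len(T_)), , drop = FALSE]
  list(out = out, cache = list(f = f$cache, b = b$cache, units = units, T_ = T_))
}

bigru_bwd <- function(dout, cache, p) {
  units <- cache$units; T_ <- cache$T_
  dHf <- dout[, , seq_len(units), drop = FALSE]
  dHb <- dout[, rev(seq_len(T_)), units + seq_len(units), drop = FALSE]
  gf <- gru_bwd(dHf, cache$f, p$fwd)
  gb <- gru_bwd(dHb, cache$b, p$bwd)
  dx <- gf$dx + gb$dx[, rev(seq_len(T_)), , drop = FALSE]
  list(dx = dx, grads = list(fwd = gf$grads, bwd = gb$grads))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
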