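# 1-D convolution with "same" padding (R wrappers over the compiled kernels)
# plus dropout. Feature maps are numeric arrays of shape
# (batch, time, channels). Stride-s layers emit ceiling(T/s) positions, with
# extra zero padding on the right when the pad is odd.

# Output length / padding arithmetic shared with the compiled code.
same_pad <- function(t_in, kernel, stride) {
  t_out <- ceiling(t_in / stride)
  pad_total <- max((t_out - 1L) * stride + kernel - t_in, 0L)
  list(t_out = as.integer(t_out),
       left = as.integer(pad_total %/% 2L),
       right = as.integer(pad_total - pad_total %/% 2L))
}

# Glorot-uniform initialization for a (kernel, c_in, filters) weight array.
conv1d_init <- function(kernel, c_in, filters, rng) {
  fan_in <- kernel * c_in
  fan_out <- kernel * filters
  limit <- sqrt(6 / (fan_in + fan_out))
  list(W = array(rng(kernel * c_in * filters, limit),
                 dim = c(kernel, c_in, filters)),
       b = numeric(filters))
}

# Forward 1-D convolution; activation "relu" or "linear".
conv1d_fwd <- function(x, W, b, stride, activation = "relu") {
  r <- conv1d_fwd_cpp(x, W, b, as.integer(stride),
                      identical(activation, "relu"))
  list(out = r$out,
       cache = list(P = r$P, out = r$out, dims = dim(x),
                    stride = as.integer(stride), activation = activation))
}

conv1d_bwd <- function(dout, cache, W) {
  d <- cache$dims
  g <- conv1d_bwd_cpp(cache$P, W, cache$stride, dout, cache$out,
                      identical(cache$activation, "relu"),
                      d[1L], d[2L], d[3L])
  list(dx = g$dx, dW = g$dW, db = as.numeric(g$db))
}

# Inverted dropout on a (B,T,C) map; mask drawn from the current RNG stream.
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate) / (1 - rate), dim = dim(x))
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dout, mask) {
  if (is.null(mask)) return(dout)
  dout * mask
}
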