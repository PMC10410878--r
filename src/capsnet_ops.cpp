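// Hot inner loops of the network: 1-D convolution (same padding, stride s),
// the GRU recurrence, and the per-capsule prediction transform. Feature maps
// cross the R boundary as (batch, time, channel) arrays (arma::cube with the
// same dimension order); internally the GRU repacks to time-major slices so
// each step touches contiguous memory. All gradient code here is pinned by
// finite-difference tests on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static void same_pad(int t_in, int k, int s, int& t_out, int& left) {
  t_out = (t_in + s - 1) / s;
  int pad_total = (t_out - 1) * s + k - t_in;
  if (pad_total < 0) pad_total = 0;
  left = pad_total / 2;
}

// Patch matrix (B*t_out) x (k*C), row index b + t*B, column index j + c*k —
// matching a weight array of dim (k, C, F) flattened column-major. Gathers
// whole strided column blocks from a zero-padded copy of each channel.
static mat im2col_cpp(const cube& x, int k, int stride, int t_out, int left) {
  const int B = x.n_rows, T = x.n_cols, C = x.n_slices;
  const int Tp = std::max((t_out - 1) * stride + k, T + left);
  mat P(B * t_out, k * C);
  mat xpc(B, Tp);
  for (int c = 0; c < C; ++c) {
    xpc.zeros();
    xpc.cols(left, left + T - 1) = x.slice(c);
    for (int j = 0; j < k; ++j) {
      const uvec pos = regspace<uvec>(j, stride, j + (t_out - 1) * stride);
      P.col(c * k + j) = vectorise(xpc.cols(pos));
    }
  }
  return P;
}

// [[Rcpp::export]]
List conv1d_fwd_cpp(const arma::cube& x, const arma::cube& W,
                    const arma::vec& b, int stride, bool relu) {
  const int B = x.n_rows, T = x.n_cols;
  const int k = W.n_rows, F = W.n_slices;
  int t_out, left;
  same_pad(T, k, stride, t_out, left);
  mat Wm(k * W.n_cols, F);
  for (int f = 0; f < F; ++f) Wm.col(f) = vectorise(W.slice(f));
  mat P = im2col_cpp(x, k, stride, t_out, left);
  mat Z = P * Wm;
  Z.each_row() += b.t();
  if (relu) Z.elem(find(Z < 0)).zeros();
  cube out(B, t_out, F);
  for (int f = 0; f < F; ++f) {
    out.slice(f) = reshape(Z.col(f), B, t_out);
  }
  return List::create(Named("out") = out, Named("P") = P);
}

// dW/db/dx from the cached patch matrix P of the forward pass.
// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::mat& P, const arma::cube& W, int stride,
                    const arma::cube& dout, const arma::cube& out, bool relu,
                    int B, int T, int C) {
  const int k = W.n_rows, F = W.n_slices;
  int t_out, left;
  same_pad(T, k, stride, t_out, left);
  mat Wm(k * C, F);
  for (int f = 0; f < F; ++f) Wm.col(f) = vectorise(W.slice(f));
  mat dZ(B * t_out, F);
  for (int f = 0; f < F; ++f) dZ.col(f) = vectorise(dout.slice(f));
  if (relu) {
    for (int f = 0; f < F; ++f) {
      dZ.col(f) %= conv_to<vec>::from(vectorise(out.slice(f)) > 0);
    }
  }
  mat dWm = P.t() * dZ;
  cube dW(k, C, F);
  for (int f = 0; f < F; ++f) dW.slice(f) = reshape(dWm.col(f), k, C);
  vec db = sum(dZ, 0).t();
  mat dP = dZ * Wm.t();
  cube dx(B, T, C);
  const int Tp = std::max((t_out - 1) * stride + k, T + left);
  mat dxp(B, Tp);
  for (int c = 0; c < C; ++c) {
    dxp.zeros();
    for (int j = 0; j < k; ++j) {
      const uvec pos = regspace<uvec>(j, stride, j + (t_out - 1) * stride);
      dxp.cols(pos) += reshape(dP.col(c * k + j), B, t_out);
    }
    dx.slice(c) = dxp.cols(left, left + T - 1);
  }
  return List::create(Named("dx") = dx, Named("dW") = dW, Named("db") = db);
}

// Repack (B, T, C) -> time-major cube with slice t = B x C matrix.
static cube to_time_major(const cube& x) {
  const int B = x.n_rows, T = x.n_cols, C = x.n_slices;
  cube xt(B, C, T);
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int t = 0; t < T; ++t) xt.slice(t).col(c) = xc.col(t);
  }
  return xt;
}

static cube from_time_major(const cube& xt) {
  const int B = xt.n_rows, C = xt.n_cols, T = xt.n_slices;
  cube x(B, T, C);
  for (int t = 0; t < T; ++t) {
    const mat& s = xt.slice(t);
    for (int c = 0; c < C; ++c) x.slice(c).col(t) = s.col(c);
  }
  return x;
}

// GRU forward over time (classical gating; see R-side docs):
//   z = sig(x Wz + h Uz + bz); r = sig(x Wr + h Ur + br)
//   g = tanh(x Wh + (r % h) Uh + bh); h' = z % h + (1 - z) % g
// Input x is (B, T, C); the returned state/gate cubes are time-major
// (B, units, T) and are consumed as-is by gru_bwd_cpp.
// [[Rcpp::export]]
List gru_fwd_cpp(const arma::cube& x,
                 const arma::mat& Wz, const arma::mat& Wr, const arma::mat& Wh,
                 const arma::mat& Uz, const arma::mat& Ur, const arma::mat& Uh,
                 const arma::vec& bz, const arma::vec& br, const arma::vec& bh) {
  const int B = x.n_rows, T = x.n_cols;
  const int U = Wz.n_cols;
  const cube xt = to_time_major(x);
  cube H(B, U, T), Zc(B, U, T), Rc(B, U, T), Gc(B, U, T);
  mat h(B, U, fill::zeros);
  for (int t = 0; t < T; ++t) {
    const mat& xs = xt.slice(t);
    mat z = xs * Wz + h * Uz;
    z.each_row() += bz.t();
    z = 1.0 / (1.0 + exp(-z));
    mat r = xs * Wr + h * Ur;
    r.each_row() += br.t();
    r = 1.0 / (1.0 + exp(-r));
    mat g = xs * Wh + (r % h) * Uh;
    g.each_row() += bh.t();
    g = tanh(g);
    h = z % h + (1.0 - z) % g;
    H.slice(t) = h;
    Zc.slice(t) = z;
    Rc.slice(t) = r;
    Gc.slice(t) = g;
  }
  return List::create(Named("H") = H, Named("Z") = Zc, Named("R") = Rc,
                      Named("G") = Gc);
}

// dH arrives time-major (B, units, T); dx returns as (B, T, C).
// [[Rcpp::export]]
List gru_bwd_cpp(const arma::cube& x, const arma::cube& dH,
                 const arma::cube& H, const arma::cube& Zc,
                 const arma::cube& Rc, const arma::cube& Gc,
                 const arma::mat& Wz, const arma::mat& Wr, const arma::mat& Wh,
                 const arma::mat& Uz, const arma::mat& Ur, const arma::mat& Uh) {
  const int B = x.n_rows, T = x.n_cols, C = x.n_slices;
  const int U = Wz.n_cols;
  const cube xt = to_time_major(x);
  cube dxt(B, C, T);
  mat dWz(C, U, fill::zeros), dWr(C, U, fill::zeros), dWh(C, U, fill::zeros);
  mat dUz(U, U, fill::zeros), dUr(U, U, fill::zeros), dUh(U, U, fill::zeros);
  vec dbz(U, fill::zeros), dbr(U, fill::zeros), dbh(U, fill::zeros);
  mat dh_next(B, U, fill::zeros);
  mat h_prev(B, U);
  for (int t = T - 1; t >= 0; --t) {
    const mat dh = dH.slice(t) + dh_next;
    const mat& z = Zc.slice(t);
    const mat& r = Rc.slice(t);
    const mat& g = Gc.slice(t);
    if (t == 0) h_prev.zeros(); else h_prev = H.slice(t - 1);
    const mat& xs = xt.slice(t);
    mat dg = dh % (1.0 - z);
    mat dz = dh % (h_prev - g);
    mat dh_prev = dh % z;
    mat da_g = dg % (1.0 - g % g);
    mat drh = da_g * Uh.t();
    mat dr = drh % h_prev;
    dh_prev += drh % r;
    mat da_z = dz % z % (1.0 - z);
    mat da_r = dr % r % (1.0 - r);
    dxt.slice(t) = da_z * Wz.t() + da_r * Wr.t() + da_g * Wh.t();
    dh_prev += da_z * Uz.t() + da_r * Ur.t();
    dWz += xs.t() * da_z;
    dWr += xs.t() * da_r;
    dWh += xs.t() * da_g;
    dUz += h_prev.t() * da_z;
    dUr += h_prev.t() * da_r;
    dUh += (r % h_prev).t() * da_g;
    dbz += sum(da_z, 0).t();
    dbr += sum(da_r, 0).t();
    dbh += sum(da_g, 0).t();
    dh_next = dh_prev;
  }
  return List::create(
    Named("dx") = from_time_major(dxt),
    Named("Wz") = dWz, Named("Wr") = dWr, Named("Wh") = dWh,
    Named("Uz") = dUz, Named("Ur") = dUr, Named("Uh") = dUh,
    Named("bz") = dbz, Named("br") = dbr, Named("bh") = dbh);
}

// Prediction vectors: uhat rows for primary capsule i (rows i*B .. i*B+B-1 of
// the (B*N) x pd matrix) times that capsule's (pd x J*D) transform.
// [[Rcpp::export]]
arma::mat caps_transform_fwd_cpp(const arma::mat& uflat,
                                 const arma::cube& route, int B) {
  const int N = route.n_slices, jd = route.n_cols;
  mat uhat(uflat.n_rows, jd);
  for (int i = 0; i < N; ++i) {
    uhat.rows(i * B, (i + 1) * B - 1) =
      uflat.rows(i * B, (i + 1) * B - 1) * route.slice(i);
  }
  return uhat;
}

// [[Rcpp::export]]
List caps_transform_bwd_cpp(const arma::mat& uflat, const arma::mat& duhat,
                            const arma::cube& route, int B) {
  const int N = route.n_slices;
  mat du(uflat.n_rows, uflat.n_cols);
  cube droute(route.n_rows, route.n_cols, N);
  for (int i = 0; i < N; ++i) {
    const mat ublock = uflat.rows(i * B, (i + 1) * B - 1);
    const mat dblock = duhat.rows(i * B, (i + 1) * B - 1);
    droute.slice(i) = ublock.t() * dblock;
    du.rows(i * B, (i + 1) * B - 1) = dblock * route.slice(i).t();
  }
  return List::create(Named("du") = du, Named("droute") = droute);
}
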