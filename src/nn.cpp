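// 3D convolution / pooling primitives for the shape-preserving denoising network.
// Layout convention: volumes are R arrays [D, H, W, C] (column-major, voxel
// index fastest); kernels are [3, 3, 3, Cin, Cout]. "Same" zero padding.
// Compute runs in single or double precision (see NetworkSpec$precision);
// values cross the R boundary as doubles either way.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

template <typename T>
static void im2col3(const T* x, int D, int H, int W, int C, arma::Mat<T>& col) {
  // col: (D*H*W) x (27*C); kernel offsets kd,kh,kw in {-1,0,1}.
  // Only the border stripes that the shifted copy cannot reach are
  // zeroed, so the buffer is written once, not twice.
  const size_t N = (size_t)D * H * W;
  col.set_size(N, 27 * (size_t)C);
  for (int c = 0; c < C; ++c) {
    const T* xc = x + (size_t)c * N;
    for (int kw = -1; kw <= 1; ++kw)
      for (int kh = -1; kh <= 1; ++kh)
        for (int kd = -1; kd <= 1; ++kd) {
          int k = (kd + 1) + 3 * (kh + 1) + 9 * (kw + 1);
          T* dst = col.colptr(k + 27 * (size_t)c);
          int d0 = std::max(0, -kd), d1 = std::min(D, D - kd);
          int h0 = std::max(0, -kh), h1 = std::min(H, H - kh);
          int w0 = std::max(0, -kw), w1 = std::min(W, W - kw);
          for (int w = 0; w < W; ++w) {
            bool wout = (w < w0 || w >= w1);
            for (int h = 0; h < H; ++h) {
              T* out = dst + (size_t)D * (h + (size_t)H * w);
              if (wout || h < h0 || h >= h1) {
                std::fill(out, out + D, (T)0);
                continue;
              }
              const T* src = xc + (size_t)(d0 + kd) +
                (size_t)D * ((h + kh) + (size_t)H * (w + kw));
              if (d0 > 0) out[0] = (T)0;
              std::copy(src, src + (d1 - d0), out + d0);
              if (d1 < D) out[D - 1] = (T)0;
            }
          }
        }
  }
}

template <typename T>
static void col2im3(const arma::Mat<T>& col, int D, int H, int W, int C, T* x) {
  const size_t N = (size_t)D * H * W;
  std::fill(x, x + N * (size_t)C, (T)0);
  for (int c = 0; c < C; ++c) {
    T* xc = x + (size_t)c * N;
    for (int kw = -1; kw <= 1; ++kw)
      for (int kh = -1; kh <= 1; ++kh)
        for (int kd = -1; kd <= 1; ++kd) {
          int k = (kd + 1) + 3 * (kh + 1) + 9 * (kw + 1);
          const T* src0 = col.colptr(k + 27 * (size_t)c);
          int d0 = std::max(0, -kd), d1 = std::min(D, D - kd);
          for (int w = std::max(0, -kw); w < std::min(W, W - kw); ++w)
            for (int h = std::max(0, -kh); h < std::min(H, H - kh); ++h) {
              T* dst = xc + (size_t)(d0 + kd) + (size_t)D * ((h + kh) + (size_t)H * (w + kw));
              const T* src = src0 + (size_t)d0 + (size_t)D * (h + (size_t)H * w);
              for (int d = 0; d < d1 - d0; ++d) dst[d] += src[d];
            }
        }
  }
}

// act: 0 = linear, 1 = relu, 2 = leaky relu (slope 0.1)
template <typename T>
static inline T act_apply(T v, int act) {
  if (act == 1) return v > 0 ? v : (T)0;
  if (act == 2) return v > 0 ? v : (T)0.1 * v;
  return v;
}
// gradient factor from the *post*-activation value (sign-preserving acts)
template <typename T>
static inline T act_factor(T post, int act) {
  if (act == 1) return post > 0 ? (T)1 : (T)0;
  if (act == 2) return post > 0 ? (T)1 : (T)0.1;
  return (T)1;
}

template <typename T>
static Rcpp::List conv3_fwd_t(Rcpp::NumericVector x, Rcpp::NumericVector wt,
                              Rcpp::NumericVector b, Rcpp::IntegerVector dims,
                              int act, bool keep_col) {
  int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3], Cout = dims[4];
  const size_t N = (size_t)D * H * W;
  arma::Mat<T> X(N, Cin);
  for (size_t i = 0; i < N * (size_t)Cin; ++i) X(i) = (T)x[i];
  arma::Mat<T>* col = new arma::Mat<T>();
  im2col3<T>(X.memptr(), D, H, W, Cin, *col);
  arma::Mat<T> Wm(27 * (size_t)Cin, Cout);
  for (size_t i = 0; i < Wm.n_elem; ++i) Wm(i) = (T)wt[i];
  arma::Mat<T> Y = (*col) * Wm;
  Rcpp::NumericVector out(N * (size_t)Cout);
  for (int c = 0; c < Cout; ++c) {
    const T* yc = Y.colptr(c);
    T bc = (T)b[c];
    double* oc = &out[0] + (size_t)c * N;
    for (size_t i = 0; i < N; ++i) oc[i] = (double)act_apply<T>(yc[i] + bc, act);
  }
  out.attr("dim") = Rcpp::IntegerVector::create(D, H, W, Cout);
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("y") = out);
  if (keep_col) {
    res["col"] = Rcpp::XPtr<arma::Mat<T>>(col, true);
  } else {
    delete col;
  }
  return res;
}

template <typename T>
static Rcpp::List conv3_bwd_t(Rcpp::NumericVector x, Rcpp::NumericVector wt,
                              Rcpp::NumericVector dy, Rcpp::NumericVector ypost,
                              Rcpp::IntegerVector dims, bool need_dx, int act,
                              SEXP col_ptr) {
  int D = dims[0], H = dims[1], W = dims[2], Cin = dims[3], Cout = dims[4];
  const size_t N = (size_t)D * H * W;
  arma::Mat<T> dY(N, Cout);
  for (size_t i = 0; i < N * (size_t)Cout; ++i)
    dY(i) = (T)dy[i] * act_factor<T>((T)ypost[i], act);
  arma::Mat<T> col_local;
  const arma::Mat<T>* colp;
  if (col_ptr != R_NilValue) {
    colp = Rcpp::XPtr<arma::Mat<T>>(col_ptr).get();
  } else {
    arma::Mat<T> X(N, Cin);
    for (size_t i = 0; i < N * (size_t)Cin; ++i) X(i) = (T)x[i];
    im2col3<T>(X.memptr(), D, H, W, Cin, col_local);
    colp = &col_local;
  }
  const arma::Mat<T>& col = *colp;
  arma::Mat<T> dW = col.t() * dY;                  // (27*Cin) x Cout
  Rcpp::NumericVector dwv(dW.n_elem), dbv(Cout);
  for (size_t i = 0; i < dW.n_elem; ++i) dwv[i] = (double)dW(i);
  for (int c = 0; c < Cout; ++c) dbv[c] = (double)arma::accu(dY.col(c));
  dwv.attr("dim") = Rcpp::IntegerVector::create(3, 3, 3, Cin, Cout);
  Rcpp::RObject dxo = R_NilValue;
  if (need_dx) {
    arma::Mat<T> Wm(27 * (size_t)Cin, Cout);
    for (size_t i = 0; i < Wm.n_elem; ++i) Wm(i) = (T)wt[i];
    arma::Mat<T> dcol = dY * Wm.t();               // N x (27*Cin)
    arma::Mat<T> dX(N, Cin);
    col2im3<T>(dcol, D, H, W, Cin, dX.memptr());
    Rcpp::NumericVector dxv(N * (size_t)Cin);
    for (size_t i = 0; i < dxv.size(); ++i) dxv[i] = (double)dX(i);
    dxv.attr("dim") = Rcpp::IntegerVector::create(D, H, W, Cin);
    dxo = dxv;
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dxo, Rcpp::Named("dW") = dwv,
                            Rcpp::Named("db") = dbv);
}

// [[Rcpp::export(name = ".conv3_fwd")]]
Rcpp::List conv3_fwd(Rcpp::NumericVector x, Rcpp::NumericVector wt,
                     Rcpp::NumericVector b, Rcpp::IntegerVector dims,
                     bool single, int act = 0, bool keep_col = false) {
  return single ? conv3_fwd_t<float>(x, wt, b, dims, act, keep_col)
                : conv3_fwd_t<double>(x, wt, b, dims, act, keep_col);
}

// [[Rcpp::export(name = ".conv3_bwd")]]
Rcpp::List conv3_bwd(Rcpp::NumericVector x, Rcpp::NumericVector wt,
                     Rcpp::NumericVector dy, Rcpp::NumericVector ypost,
                     Rcpp::IntegerVector dims, bool single,
                     bool need_dx = true, int act = 0,
                     SEXP col_ptr = R_NilValue) {
  return single ? conv3_bwd_t<float>(x, wt, dy, ypost, dims, need_dx, act, col_ptr)
                : conv3_bwd_t<double>(x, wt, dy, ypost, dims, need_dx, act, col_ptr);
}

// 2x average pooling, truncating odd trailing voxels is disallowed upstream.
// [[Rcpp::export(name = ".pool2_fwd")]]
Rcpp::NumericVector pool2_fwd(Rcpp::NumericVector x, Rcpp::IntegerVector dims) {
  int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  Rcpp::NumericVector out((size_t)Do * Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double s = 0;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd)
                s += x[(size_t)(2 * d + kd) + (size_t)D * ((2 * h + kh) + (size_t)H * ((2 * w + kw) + (size_t)W * c))];
          out[(size_t)d + (size_t)Do * (h + (size_t)Ho * (w + (size_t)Wo * c))] = s / 8.0;
        }
  out.attr("dim") = Rcpp::IntegerVector::create(Do, Ho, Wo, C);
  return out;
}

// [[Rcpp::export(name = ".pool2_bwd")]]
Rcpp::NumericVector pool2_bwd(Rcpp::NumericVector dy, Rcpp::IntegerVector dims) {
  int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  int Do = D / 2, Ho = H / 2, Wo = W / 2;
  Rcpp::NumericVector out((size_t)D * H * W * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double g = dy[(size_t)d + (size_t)Do * (h + (size_t)Ho * (w + (size_t)Wo * c))] / 8.0;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd)
                out[(size_t)(2 * d + kd) + (size_t)D * ((2 * h + kh) + (size_t)H * ((2 * w + kw) + (size_t)W * c))] = g;
        }
  out.attr("dim") = dims;
  return out;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export(name = ".up2_fwd")]]
Rcpp::NumericVector up2_fwd(Rcpp::NumericVector x, Rcpp::IntegerVector dims) {
  int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  int Do = D * 2, Ho = H * 2, Wo = W * 2;
  Rcpp::NumericVector out((size_t)Do * Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d)
          out[(size_t)d + (size_t)Do * (h + (size_t)Ho * (w + (size_t)Wo * c))] =
            x[(size_t)(d / 2) + (size_t)D * ((h / 2) + (size_t)H * ((w / 2) + (size_t)W * c))];
  out.attr("dim") = Rcpp::IntegerVector::create(Do, Ho, Wo, C);
  return out;
}

// [[Rcpp::export(name = ".up2_bwd")]]
Rcpp::NumericVector up2_bwd(Rcpp::NumericVector dy, Rcpp::IntegerVector dims) {
  // dims are the dims of the *input* of up2_fwd
  int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  int Do = D * 2, Ho = H * 2, Wo = W * 2;
  Rcpp::NumericVector out((size_t)D * H * W * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d)
          out[(size_t)(d / 2) + (size_t)D * ((h / 2) + (size_t)H * ((w / 2) + (size_t)W * c))] +=
            dy[(size_t)d + (size_t)Do * (h + (size_t)Ho * (w + (size_t)Wo * c))];
  out.attr("dim") = dims;
  return out;
}

// Signed-permutation transform of a cubic volume: out[j1,j2,j3] =
// v[off1[j1] + off2[j2] + off3[j3] + 1], with per-axis offset tables
// precomputed in R. One gather pass instead of two indexed copies.
// [[Rcpp::export(name = ".sperm3")]]
Rcpp::NumericVector sperm3(Rcpp::NumericVector v, Rcpp::IntegerVector off1,
                           Rcpp::IntegerVector off2, Rcpp::IntegerVector off3) {
  int n = off1.size();
  Rcpp::NumericVector out((size_t)n * n * n);
  const double* src = &v[0];
  double* dst = &out[0];
  size_t pos = 0;
  for (int j3 = 0; j3 < n; ++j3)
    for (int j2 = 0; j2 < n; ++j2) {
      size_t base = (size_t)off2[j2] + (size_t)off3[j3];
      for (int j1 = 0; j1 < n; ++j1) dst[pos++] = src[base + off1[j1]];
    }
  out.attr("dim") = v.attr("dim");
  return out;
}
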