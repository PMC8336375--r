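// Dense-tensor primitives for the CNN: stride-1 zero-padded 2-D convolution
// via im2col + GEMM, 2x2 max pooling, and kxk average pooling. Tensors are
// R arrays in (H, W, C, N) column-major layout; convolution kernels are
// (k, k, Cin, Cout). All ops return shapes consistent with stride-1
// convolution (H_out = H + 2*pad - k + 1) or exact-division pooling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-D (H,W,C,N) array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Gather zero-padded patches of sample `xs` (H x W x C) into `cols`
// (Ho*Wo rows, k*k*C columns; patch positions vary fastest so every fill is
// a sequential copy). Convolution arithmetic is templated on precision:
// training uses single-precision GEMMs (they dominate run time and float is
// ample for conv activations/gradients); double precision is available for
// exact numerical verification.
template <typename eT>
static void im2col(const double* xs, int H, int W, int C, int k, int pad,
                   int Ho, int Wo, arma::Mat<eT>& cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xs + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        eT* dcol = cols.colptr(col);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow + kw - pad;
          if (iw < 0 || iw >= W) continue;
          const int oh_lo = std::max(0, pad - kh);
          const int oh_hi = std::min(Ho, H + pad - kh);
          if (oh_hi <= oh_lo) continue;
          const double* src = xc + (size_t)iw * H + (oh_lo + kh - pad);
          eT* dst = dcol + oh_lo + (size_t)ow * Ho;
          for (int oh = oh_lo; oh < oh_hi; ++oh) *dst++ = (eT)*src++;
        }
      }
    }
  }
}

// Scatter-add patch-gradient columns back into the image gradient.
template <typename eT>
static void col2im(const arma::Mat<eT>& cols, int H, int W, int C, int k,
                   int pad, int Ho, int Wo, double* dxs) {
  for (int c = 0; c < C; ++c) {
    double* xc = dxs + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        const eT* scol = cols.colptr(col);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow + kw - pad;
          if (iw < 0 || iw >= W) continue;
          const int oh_lo = std::max(0, pad - kh);
          const int oh_hi = std::min(Ho, H + pad - kh);
          if (oh_hi <= oh_lo) continue;
          double* dst = xc + (size_t)iw * H + (oh_lo + kh - pad);
          const eT* src = scol + oh_lo + (size_t)ow * Ho;
          for (int oh = oh_lo; oh < oh_hi; ++oh) *dst++ += *src++;
        }
      }
    }
  }
}

template <typename eT>
static NumericVector conv2d_forward_impl(const NumericVector& x,
                                         const NumericVector& w,
                                         const NumericVector& b, int pad) {
  int xd[4], wd[4];
  get_dims(x, xd); get_dims(w, wd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k || Cin != C) stop("kernel/channel mismatch in conv forward");
  const int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  if (Ho <= 0 || Wo <= 0) stop("conv output would be empty");
  NumericVector y(no_init((size_t)Ho * Wo * Cout * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::Mat<eT> Wm = arma::conv_to<arma::Mat<eT>>::from(
      arma::mat(const_cast<double*>(w.begin()), (size_t)k * k * Cin, Cout,
                false, true));
  arma::Mat<eT> cols((size_t)Ho * Wo, (size_t)k * k * C);
  arma::Mat<eT> out((size_t)Ho * Wo, Cout);
  for (int n = 0; n < N; ++n) {
    im2col<eT>(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, Ho, Wo,
               cols);
    out = cols * Wm;
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    const size_t hw = (size_t)Ho * Wo;
    for (int co = 0; co < Cout; ++co) {
      const eT* op = out.colptr(co);
      const double bc = b[co];
      for (size_t i = 0; i < hw; ++i) yp[co * hw + i] = op[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int pad,
                                 bool use_double = false) {
  return use_double ? conv2d_forward_impl<double>(x, w, b, pad)
                    : conv2d_forward_impl<float>(x, w, b, pad);
}

template <typename eT>
static List conv2d_backward_impl(const NumericVector& x,
                                 const NumericVector& w,
                                 const NumericVector& dy, int pad) {
  int xd[4], wd[4], yd[4];
  get_dims(x, xd); get_dims(w, wd); get_dims(dy, yd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv((size_t)k * k * C * Cout);
  dwv.attr("dim") = IntegerVector::create(k, k, C, Cout);
  NumericVector dbv(Cout);
  const arma::Mat<eT> Wm = arma::conv_to<arma::Mat<eT>>::from(
      arma::mat(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout,
                false, true));
  arma::Mat<eT> dW((size_t)k * k * C, Cout, arma::fill::zeros);
  arma::colvec db(dbv.begin(), Cout, false, true);
  arma::Mat<eT> cols((size_t)Ho * Wo, (size_t)k * k * C);
  arma::Mat<eT> dYf((size_t)Ho * Wo, Cout);
  for (int n = 0; n < N; ++n) {
    const arma::mat dYm(const_cast<double*>(dy.begin()) +
                        (size_t)n * Ho * Wo * Cout,
                        (size_t)Ho * Wo, Cout, false, true);
    dYf = arma::conv_to<arma::Mat<eT>>::from(dYm);
    im2col<eT>(x.begin() + (size_t)n * H * W * C, H, W, C, k, pad, Ho, Wo,
               cols);
    dW += cols.t() * dYf;
    db += arma::sum(dYm, 0).t();
    arma::Mat<eT> dcols = dYf * Wm.t();
    col2im<eT>(dcols, H, W, C, k, pad, Ho, Wo,
               dx.begin() + (size_t)n * H * W * C);
  }
  arma::mat dWd(dwv.begin(), (size_t)k * k * C, Cout, false, true);
  dWd = arma::conv_to<arma::mat>::from(dW);
  return List::create(Named("dx") = dx, Named("dw") = dwv, Named("db") = dbv);
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int pad, bool use_double = false) {
  return use_double ? conv2d_backward_impl<double>(x, w, dy, pad)
                    : conv2d_backward_impl<float>(x, w, dy, pad);
}

// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  int d[4];
  get_dims(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // 1-based index into x
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          const size_t base = (size_t)(2 * ow) * H + 2 * oh;
          size_t best = base;
          double v = xc[base];
          if (xc[base + 1] > v) { v = xc[base + 1]; best = base + 1; }
          if (xc[base + H] > v) { v = xc[base + H]; best = base + H; }
          if (xc[base + H + 1] > v) { v = xc[base + H + 1]; best = base + H + 1; }
          y[o] = v;
          idx[o] = (int)(((size_t)n * C + c) * H * W + best) + 1;
          ++o;
        }
    }
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    IntegerVector xdim) {
  size_t total = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(total);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_forward(NumericVector x, int k) {
  int d[4];
  get_dims(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % k || W % k) stop("average pooling requires divisible spatial dims");
  const int Ho = H / k, Wo = W / k;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / (k * k);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double s = 0;
          for (int j = 0; j < k; ++j) {
            const double* col = xc + (size_t)(k * ow + j) * H + k * oh;
            for (int i = 0; i < k; ++i) s += col[i];
          }
          y[o++] = s * inv;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_backward(NumericVector dy, int k) {
  int d[4];
  get_dims(dy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = Ho * k, W = Wo * k;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double inv = 1.0 / (k * k);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + ((size_t)n * C + c) * H * W;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          const double g = dy[o++] * inv;
          for (int j = 0; j < k; ++j) {
            double* col = xc + (size_t)(k * ow + j) * H + k * oh;
            for (int i = 0; i < k; ++i) col[i] += g;
          }
        }
    }
  return dx;
}

// Fused batch-normalization + ReLU. In training mode batch statistics are
// computed per channel over (H, W, N); in eval mode the supplied running
// statistics are used. Returns the post-ReLU activations plus the
// normalized values and inverse standard deviations needed for backward.
// [[Rcpp::export]]
List cpp_bnrelu_forward(NumericVector x, NumericVector gamma,
                        NumericVector beta, NumericVector mean_in,
                        NumericVector var_in, bool train, double eps) {
  int d[4];
  get_dims(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  NumericVector mu(C), var(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * hw;
        for (size_t i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      const double m = s / (hw * N);
      mu[c] = m;
      var[c] = std::max(s2 / (hw * N) - m * m, 0.0);
    }
  } else {
    mu = clone(mean_in);
    var = clone(var_in);
  }
  NumericVector y(no_init(x.size())), xhat(no_init(x.size())), invstd(C);
  y.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(var[c] + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c], m = mu[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* xc = x.begin() + off;
      double* xh = xhat.begin() + off;
      double* yc = y.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        const double xn = (xc[i] - m) * is;
        xh[i] = xn;
        const double v = g * xn + b;
        yc[i] = v > 0 ? v : 0;
      }
    }
  }
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("invstd") = invstd, Named("mean") = mu,
                      Named("var") = var);
}

// Backward through ReLU then batch normalization (training statistics).
// [[Rcpp::export]]
List cpp_bnrelu_backward(NumericVector dy, NumericVector y,
                         NumericVector xhat, NumericVector gamma,
                         NumericVector invstd) {
  int d[4];
  get_dims(dy, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  NumericVector dx(no_init(dy.size())), dgamma(C), dbeta(C);
  dx.attr("dim") = dy.attr("dim");
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* dyc = dy.begin() + off;
      const double* yc = y.begin() + off;
      const double* xh = xhat.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        if (yc[i] > 0) { s1 += dyc[i]; s2 += dyc[i] * xh[i]; }
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double a = gamma[c] * invstd[c];
    const double c1 = s1 / m, c2 = s2 / m;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double* dyc = dy.begin() + off;
      const double* yc = y.begin() + off;
      const double* xh = xhat.begin() + off;
      double* dxc = dx.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        const double g = yc[i] > 0 ? dyc[i] : 0;
        dxc[i] = a * (g - c1 - xh[i] * c2);
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
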