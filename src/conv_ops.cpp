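// im2col-based 2D convolution and transposed convolution kernels.
// Array layout follows R column-major order: activations are [H, W, C, N],
// convolution weights [k, k, Cin, Cout], transposed-conv weights [k, k, Cout, Cin].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out_dim(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Unfold one [H, W, C] image into a [Ho*Wo, k*k*C] patch matrix.
// Row index r = ho + Ho*wo; column index kidx = i + k*(j + k*c), which matches
// the column-major flattening of a [k, k, C, Co] weight array.
static void im2col(const double* x, int H, int W, int C,
                   int k, int s, int p, int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int kidx = i + k * (j + k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + j;
          const bool w_ok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + i;
            double v = 0.0;
            if (w_ok && hi >= 0 && hi < H)
              v = x[hi + (size_t)H * (wi + (size_t)W * c)];
            col(ho + (size_t)Ho * wo, kidx) = v;
          }
        }
      }
    }
  }
}

// Adjoint of im2col: scatter-add a patch matrix back into a zeroed [H, W, C] image.
static void col2im(const arma::mat& col, int H, int W, int C,
                   int k, int s, int p, int Ho, int Wo, double* x) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int kidx = i + k * (j + k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s - p + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s - p + i;
            if (hi < 0 || hi >= H) continue;
            x[hi + (size_t)H * (wi + (size_t)W * c)] += col(ho + (size_t)Ho * wo, kidx);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w, int stride, int pad) {
  IntegerVector xd = x.attr("dim");  // H, W, Ci, N
  IntegerVector wd = w.attr("dim");  // k, k, Ci, Co
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int k = wd[0], Co = wd[3];
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Ci, Co, false, true);
  NumericVector y((size_t)Ho * Wo * Co * N);
  arma::mat col((size_t)Ho * Wo, (size_t)k * k * Ci);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, k, stride, pad, Ho, Wo, col);
    arma::mat ym(y.begin() + (size_t)Ho * Wo * Co * n, (size_t)Ho * Wo, Co, false, true);
    ym = col * Wm;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int k = wd[0], Co = wd[3];
  const int Ho = conv_out_dim(H, k, stride, pad);
  const int Wo = conv_out_dim(W, k, stride, pad);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Ci, Co, false, true);
  NumericVector gx((size_t)H * W * Ci * N);   // zero-initialised
  NumericVector gw((size_t)k * k * Ci * Co);
  arma::mat gWm(gw.begin(), (size_t)k * k * Ci, Co, false, true);
  arma::mat col((size_t)Ho * Wo, (size_t)k * k * Ci);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * Ci * n, H, W, Ci, k, stride, pad, Ho, Wo, col);
    arma::mat gym(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Co * n,
                  (size_t)Ho * Wo, Co, false, true);
    gWm += col.t() * gym;
    arma::mat gcol = gym * Wm.t();
    col2im(gcol, H, W, Ci, k, stride, pad, Ho, Wo, gx.begin() + (size_t)H * W * Ci * n);
  }
  gx.attr("dim") = IntegerVector::create(H, W, Ci, N);
  gw.attr("dim") = IntegerVector::create(k, k, Ci, Co);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Transposed convolution: the data-adjoint of a stride-s convolution.
// Output spatial dim: (in - 1)*stride - 2*pad + k.
// [[Rcpp::export]]
NumericVector cpp_convt_forward(NumericVector x, NumericVector w, int stride, int pad) {
  IntegerVector xd = x.attr("dim");  // H, W, Ci, N
  IntegerVector wd = w.attr("dim");  // k, k, Co, Ci
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int k = wd[0], Co = wd[2];
  const int Ho = (H - 1) * stride - 2 * pad + k;
  const int Wo = (W - 1) * stride - 2 * pad + k;
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Co, Ci, false, true);
  NumericVector y((size_t)Ho * Wo * Co * N);  // zero-initialised
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)H * W * Ci * n,
                 (size_t)H * W, Ci, false, true);
    arma::mat gcol = xm * Wm.t();  // [H*W, k*k*Co]
    col2im(gcol, Ho, Wo, Co, k, stride, pad, H, W, y.begin() + (size_t)Ho * Wo * Co * n);
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  return y;
}

// [[Rcpp::export]]
List cpp_convt_backward(NumericVector x, NumericVector w, NumericVector gy,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int k = wd[0], Co = wd[2];
  const int Ho = (H - 1) * stride - 2 * pad + k;
  const int Wo = (W - 1) * stride - 2 * pad + k;
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * Co, Ci, false, true);
  NumericVector gx((size_t)H * W * Ci * N);
  NumericVector gw((size_t)k * k * Co * Ci);
  arma::mat gWm(gw.begin(), (size_t)k * k * Co, Ci, false, true);
  arma::mat col((size_t)H * W, (size_t)k * k * Co);
  for (int n = 0; n < N; ++n) {
    im2col(gy.begin() + (size_t)Ho * Wo * Co * n, Ho, Wo, Co, k, stride, pad, H, W, col);
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)H * W * Ci * n,
                 (size_t)H * W, Ci, false, true);
    arma::mat gxm(gx.begin() + (size_t)H * W * Ci * n, (size_t)H * W, Ci, false, true);
    gxm = col * Wm;
    gWm += col.t() * xm;
  }
  gx.attr("dim") = IntegerVector::create(H, W, Ci, N);
  gw.attr("dim") = IntegerVector::create(k, k, Co, Ci);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}
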