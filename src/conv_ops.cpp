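// im2col / col2im convolution kernels for HWC feature maps.
//
// Feature maps are arma::cube with (rows, cols, slices) = (H, W, C), which is
// memory-compatible with an R array of dim c(H, W, C). Convolution weights
// are flattened to a (k*k*Cin) x Cout matrix; the row index runs kh fastest,
// then kw, then input channel, matching an R array of dim c(k, k, Cin, Cout).
// The backward pass recomputes im2col from the saved input rather than
// shipping the (large) column matrix through R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_extent(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static mat im2col_impl(const cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_extent(H, k, stride, pad);
  const int Wo = out_extent(W, k, stride, pad);
  mat cols(Ho * (size_t)Wo, (size_t)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        double* dst = cols.colptr(col);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          const double* src = x.slice_colptr(c, iw);
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            dst[oh + (size_t)Ho * ow] = src[ih];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::mat im2col_hwc(const arma::cube& x, int k, int stride, int pad) {
  return im2col_impl(x, k, stride, pad);
}

// Forward convolution; act = 1 fuses a SiLU (x * sigmoid(x)) activation.
// [[Rcpp::export]]
arma::cube conv2d_fw(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b, int k, int stride, int pad,
                     int act = 0) {
  const int Ho = out_extent(x.n_rows, k, stride, pad);
  const int Wo = out_extent(x.n_cols, k, stride, pad);
  mat y = im2col_impl(x, k, stride, pad) * w;
  y.each_row() += b.t();
  if (act) y = y % (1.0 / (1.0 + exp(-y)));
  return cube(y.memptr(), Ho, Wo, w.n_cols);
}

// [[Rcpp::export]]
Rcpp::List conv2d_bw(const arma::cube& x, const arma::cube& gout,
                     const arma::mat& w, const arma::vec& b, int k,
                     int stride, int pad, int act = 0) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = gout.n_rows, Wo = gout.n_cols, Cout = gout.n_slices;
  const mat cols = im2col_impl(x, k, stride, pad);
  mat gy(const_cast<double*>(gout.memptr()), (size_t)Ho * Wo, Cout,
         false, true);
  mat gy_act;
  if (act) {
    mat pre = cols * w;
    pre.each_row() += b.t();
    const mat s = 1.0 / (1.0 + exp(-pre));
    gy_act = gy % (s % (1.0 + pre % (1.0 - s)));
    gy = mat(gy_act.memptr(), gy_act.n_rows, gy_act.n_cols, false, true);
  }
  mat gw = cols.t() * gy;
  vec gb = sum(gy, 0).t();
  mat gcols = gy * w.t();
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int col = kh + k * kw + k * k * c;
        const double* src = gcols.colptr(col);
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          double* dst = gx.slice_colptr(c, iw);
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * stride - pad + kh;
            if (ih < 0 || ih >= H) continue;
            dst[ih] += src[oh + (size_t)Ho * ow];
          }
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
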