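// GEMM-based 2D convolution primitives (im2col) used by the neural
// networks. Single image layout: (H, W, C) cubes; kernels: (kh*kw*C, OC)
// matrices with the im2col ordering produced here (dh fastest, then dw,
// then channel). The patch matrix is kept transposed (Ho*Wo x kh*kw*C) so
// the hot loops run over contiguous memory.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int clamp_lo(int num, int den) {
  // smallest i >= 0 with i*den >= num
  if (num <= 0) return 0;
  return (num + den - 1) / den;
}

static arma::mat im2col_t(const arma::cube& x, int kh, int kw, int stride,
                          int pad, int& ho, int& wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  ho = (H + 2 * pad - kh) / stride + 1;
  wo = (W + 2 * pad - kw) / stride + 1;
  arma::mat cols(ho * wo, kh * kw * C, arma::fill::zeros);
  double* cp = cols.memptr();
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int colidx = dh + kh * (dw + kw * c);
        double* dst = cp + (size_t)colidx * ho * wo;
        const int i0 = clamp_lo(pad - dh, stride);
        const int i1 = (H - 1 + pad - dh) / stride;  // inclusive
        const int j0 = clamp_lo(pad - dw, stride);
        const int j1 = (W - 1 + pad - dw) / stride;
        for (int j = j0; j <= j1 && j < wo; ++j) {
          const int wj = j * stride - pad + dw;
          const double* src = xc + (size_t)wj * H;
          double* d = dst + (size_t)j * ho;
          if (stride == 1) {
            const int hi0 = i0 * 1 - pad + dh;
            for (int i = i0; i <= i1 && i < ho; ++i)
              d[i] = src[hi0 + (i - i0)];
          } else {
            for (int i = i0; i <= i1 && i < ho; ++i)
              d[i] = src[i * stride - pad + dh];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_t(const arma::mat& cols, int H, int W, int C, int kh,
                     int kw, int stride, int pad, int ho, int wo,
                     arma::cube& out) {
  out.zeros(H, W, C);
  const double* cp = cols.memptr();
  for (int c = 0; c < C; ++c) {
    double* xc = out.slice_memptr(c);
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int colidx = dh + kh * (dw + kw * c);
        const double* src0 = cp + (size_t)colidx * ho * wo;
        const int i0 = clamp_lo(pad - dh, stride);
        const int i1 = (H - 1 + pad - dh) / stride;
        const int j0 = clamp_lo(pad - dw, stride);
        const int j1 = (W - 1 + pad - dw) / stride;
        for (int j = j0; j <= j1 && j < wo; ++j) {
          const int wj = j * stride - pad + dw;
          double* dstc = xc + (size_t)wj * H;
          const double* s = src0 + (size_t)j * ho;
          for (int i = i0; i <= i1 && i < ho; ++i)
            dstc[i * stride - pad + dh] += s[i];
        }
      }
    }
  }
}

// Forward: y(ho,wo,oc) = conv(x, W) + bias
// [[Rcpp::export(name = ".conv2d_fw_cpp")]]
arma::cube conv2d_fw_cpp(const arma::cube& x, const arma::mat& w,
                         const arma::vec& bias, int kh, int kw, int stride,
                         int pad) {
  int ho, wo;
  arma::mat cols = im2col_t(x, kh, kw, stride, pad, ho, wo);
  arma::mat y = cols * w;  // (ho*wo) x OC
  const int oc = w.n_cols;
  arma::cube out(ho, wo, oc);
  for (int c = 0; c < oc; ++c) {
    std::memcpy(out.slice_memptr(c), y.colptr(c),
                sizeof(double) * ho * wo);
    if (bias[c] != 0.0) out.slice(c) += bias[c];
  }
  return out;
}

// Backward: returns list(dx, dw, db) for upstream gradient dy.
// [[Rcpp::export(name = ".conv2d_bw_cpp")]]
List conv2d_bw_cpp(const arma::cube& x, const arma::mat& w,
                   const arma::cube& dy, int kh, int kw, int stride, int pad,
                   bool need_dx) {
  int ho, wo;
  arma::mat cols = im2col_t(x, kh, kw, stride, pad, ho, wo);
  const int oc = dy.n_slices;
  arma::mat dymat(ho * wo, oc);
  for (int c = 0; c < oc; ++c) {
    std::memcpy(dymat.colptr(c), dy.slice_memptr(c),
                sizeof(double) * ho * wo);
  }
  arma::mat dw = cols.t() * dymat;       // (kh*kw*C) x OC
  arma::vec db = arma::sum(dymat, 0).t();
  arma::cube dx;
  if (need_dx) {
    arma::mat dcols = dymat * w.t();     // (ho*wo) x (kh*kw*C)
    col2im_t(dcols, x.n_rows, x.n_cols, x.n_slices, kh, kw, stride, pad,
             ho, wo, dx);
  } else {
    dx.zeros(1, 1, 1);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
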