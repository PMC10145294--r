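// Low-level numerical kernels for the segmentation networks.
//
// Feature maps are passed as arma::cube with layout (H, W, C), matching an
// R array of dim c(H, W, C).  im2col rows are ordered h-fastest
// (p = ho + Ho*wo) so that the (Ho*Wo) x Cout product of the column matrix
// with a flattened kernel reshapes straight back into an R array
// c(Ho, Wo, Cout).  Column order within a row is (kh, kw, cin), kh fastest,
// matching the column-major flattening of an R kernel array
// c(kh, kw, cin, cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int dil, int pad) {
  int eff = dil * (k - 1) + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::cube& x, int kh, int kw,
                     int stride, int dil, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, kh, stride, dil, pad);
  const int Wo = out_size(W, kw, stride, dil, pad);
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  arma::mat cols(Ho * Wo, kh * kw * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ikw = 0; ikw < kw; ++ikw) {
      for (int ikh = 0; ikh < kh; ++ikh) {
        const int col = ikh + kh * (ikw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + ikw * dil;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ikh * dil;
            if (h < 0 || h >= H) continue;
            cols(ho + Ho * wo, col) = x(h, w, c);
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter column-matrix gradients back onto the
// input grid (accumulating where patches overlap).
// [[Rcpp::export]]
arma::cube cpp_col2im(const arma::mat& cols, int H, int W, int C,
                      int kh, int kw, int stride, int dil, int pad) {
  const int Ho = out_size(H, kh, stride, dil, pad);
  const int Wo = out_size(W, kw, stride, dil, pad);
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ikw = 0; ikw < kw; ++ikw) {
      for (int ikh = 0; ikh < kh; ++ikh) {
        const int col = ikh + kh * (ikw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + ikw * dil;
          if (w < 0 || w >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ikh * dil;
            if (h < 0 || h >= H) continue;
            gx(h, w, c) += cols(ho + Ho * wo, col);
          }
        }
      }
    }
  }
  return gx;
}

struct LinWeights {
  arma::ivec i0, i1;
  arma::vec w0, w1;
};

// Corner-aligned source coordinates: output index i maps to
// i * (n_in - 1) / (n_out - 1); a singleton axis maps to index 0.
static LinWeights lin_weights(int n_in, int n_out) {
  LinWeights lw;
  lw.i0.set_size(n_out); lw.i1.set_size(n_out);
  lw.w0.set_size(n_out); lw.w1.set_size(n_out);
  for (int i = 0; i < n_out; ++i) {
    double s = (n_out > 1) ? (double)i * (n_in - 1) / (n_out - 1) : 0.0;
    int i0 = (int)std::floor(s);
    if (i0 > n_in - 2) i0 = std::max(n_in - 2, 0);
    int i1 = std::min(i0 + 1, n_in - 1);
    double f = s - i0;
    lw.i0[i] = i0; lw.i1[i] = i1;
    lw.w0[i] = 1.0 - f; lw.w1[i] = f;
  }
  return lw;
}

// [[Rcpp::export]]
arma::cube cpp_bilinear_resize(const arma::cube& x, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  LinWeights lh = lin_weights(H, Ho), lw = lin_weights(W, Wo);
  arma::cube y(Ho, Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) =
          lh.w0[i] * (lw.w0[j] * x(lh.i0[i], lw.i0[j], c) +
                      lw.w1[j] * x(lh.i0[i], lw.i1[j], c)) +
          lh.w1[i] * (lw.w0[j] * x(lh.i1[i], lw.i0[j], c) +
                      lw.w1[j] * x(lh.i1[i], lw.i1[j], c));
  return y;
}

// Adjoint of cpp_bilinear_resize for gradient back-propagation.
// [[Rcpp::export]]
arma::cube cpp_bilinear_resize_grad(const arma::cube& gy, int H, int W) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  LinWeights lh = lin_weights(H, Ho), lw = lin_weights(W, Wo);
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = gy(i, j, c);
        gx(lh.i0[i], lw.i0[j], c) += lh.w0[i] * lw.w0[j] * g;
        gx(lh.i0[i], lw.i1[j], c) += lh.w0[i] * lw.w1[j] * g;
        gx(lh.i1[i], lw.i0[j], c) += lh.w1[i] * lw.w0[j] * g;
        gx(lh.i1[i], lw.i1[j], c) += lh.w1[i] * lw.w1[j] * g;
      }
  return gx;
}
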