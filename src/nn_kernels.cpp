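// Low-level kernels for the compact feed-forward networks: image-to-column
// unrolling (turning 2D convolution into one BLAS matrix product), its
// adjoint, and 2x2 max-pooling with argmax bookkeeping for backprop.
#include <Rcpp.h>
using namespace Rcpp;

// arr: [H, W, C, N] column-major. Result: (kh*kw*C) x (oh*ow*N); output
// columns are ordered with the output row index fastest, then output
// column, then image.
// [[Rcpp::export]]
NumericMatrix nn_im2col(NumericVector arr, int kh, int kw) {
  IntegerVector d = arr.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = H - kh + 1, ow = W - kw + 1;
  const int rowlen = kh * kw * C;
  NumericMatrix out(rowlen, oh * ow * N);
  const double *a = arr.begin();
  double *o = out.begin();
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const R_xlen_t col = (R_xlen_t)n * oh * ow + (R_xlen_t)j * oh + i;
        double *oc = o + col * rowlen;
        int r = 0;
        for (int c = 0; c < C; ++c) {
          const double *base = a + (R_xlen_t)c * H * W + (R_xlen_t)n * H * W * C;
          for (int q = 0; q < kw; ++q)
            for (int p = 0; p < kh; ++p)
              oc[r++] = base[(i + p) + (R_xlen_t)(j + q) * H];
        }
      }
  return out;
}

// adjoint of nn_im2col: scatter-add column gradients back onto the image
// [[Rcpp::export]]
NumericVector nn_col2im(NumericMatrix cols, int H, int W, int C, int N,
                        int kh, int kw) {
  const int oh = H - kh + 1, ow = W - kw + 1;
  NumericVector arr((R_xlen_t)H * W * C * N);
  arr.attr("dim") = IntegerVector::create(H, W, C, N);
  double *a = arr.begin();
  const double *o = cols.begin();
  const int rowlen = kh * kw * C;
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const R_xlen_t col = (R_xlen_t)n * oh * ow + (R_xlen_t)j * oh + i;
        const double *oc = o + col * rowlen;
        int r = 0;
        for (int c = 0; c < C; ++c) {
          double *base = a + (R_xlen_t)c * H * W + (R_xlen_t)n * H * W * C;
          for (int q = 0; q < kw; ++q)
            for (int p = 0; p < kh; ++p)
              base[(i + p) + (R_xlen_t)(j + q) * H] += oc[r++];
        }
      }
  return arr;
}

// 2x2 max pooling with stride 2; odd trailing rows/columns are dropped.
// Returns the pooled array and the 1-based linear argmax index per output.
// [[Rcpp::export]]
List nn_maxpool2(NumericVector arr) {
  IntegerVector d = arr.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = H / 2, ow = W / 2;
  NumericVector out((R_xlen_t)oh * ow * C * N);
  out.attr("dim") = IntegerVector::create(oh, ow, C, N);
  IntegerVector idx(oh * (R_xlen_t)ow * C * N);
  const double *a = arr.begin();
  double *o = out.begin();
  R_xlen_t k = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (R_xlen_t)c * H * W + (R_xlen_t)n * H * W * C;
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          R_xlen_t best = off + (2 * i) + (R_xlen_t)(2 * j) * H;
          double bv = a[best];
          const R_xlen_t cand[3] = {best + 1, best + H, best + H + 1};
          for (int t = 0; t < 3; ++t)
            if (a[cand[t]] > bv) { bv = a[cand[t]]; best = cand[t]; }
          o[k] = bv;
          idx[k] = (int)(best + 1);
          ++k;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_bwd(NumericVector gout, IntegerVector idx,
                              IntegerVector dims_in) {
  NumericVector gin((R_xlen_t)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3]);
  gin.attr("dim") = dims_in;
  double *g = gin.begin();
  for (R_xlen_t k = 0; k < gout.size(); ++k) g[idx[k] - 1] += gout[k];
  return gin;
}
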