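// Temporal (1-D) convolution kernels for the classifier engine.
//
// Batches are (L, C, N) cubes: time x channels x batch, matching R's array
// layout.  Weights are (F, k*C) with column index a + c*k (position within
// kernel fastest), matching the R-side initializers.  The forward pass
// returns the im2col matrix so the backward pass can reuse it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List conv1d_fwd_cpp(const arma::cube& x, const arma::mat& W,
                    const arma::vec& b, int stride, int pad_l, int pad_r) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int k = W.n_cols / C;
  const int F = W.n_rows;
  const int Lp = L + pad_l + pad_r;
  if (Lp < k) stop("input length shorter than kernel");
  const int Lo = (Lp - k) / stride + 1;

  arma::mat xc(k * C, (size_t)Lo * N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.slice_memptr(n);
    for (int j = 0; j < Lo; ++j) {
      double* col = xc.colptr((size_t)n * Lo + j);
      const int start = j * stride - pad_l;
      for (int c = 0; c < C; ++c) {
        const double* xcol = xs + (size_t)c * L;
        double* dst = col + (size_t)c * k;
        for (int a = 0; a < k; ++a) {
          const int t = start + a;
          dst[a] = (t >= 0 && t < L) ? xcol[t] : 0.0;
        }
      }
    }
  }
  arma::mat y = W * xc;
  y.each_col() += b;
  arma::cube out(Lo, F, N);
  for (int n = 0; n < N; ++n) {
    out.slice(n) = y.cols((size_t)n * Lo, (size_t)n * Lo + Lo - 1).t();
  }
  return List::create(_["out"] = out, _["xc"] = xc);
}

// [[Rcpp::export]]
List conv1d_bwd_cpp(const arma::cube& dout, const arma::mat& W,
                    const arma::mat& xc, int L, int C, int stride,
                    int pad_l) {
  const int Lo = dout.n_rows, F = dout.n_cols, N = dout.n_slices;
  const int k = W.n_cols / C;

  arma::mat dy(F, (size_t)Lo * N);
  for (int n = 0; n < N; ++n) {
    dy.cols((size_t)n * Lo, (size_t)n * Lo + Lo - 1) = dout.slice(n).t();
  }
  arma::mat dW = dy * xc.t();
  arma::vec db = arma::sum(dy, 1);
  arma::mat dxc = W.t() * dy;             // kC x LoN

  arma::cube dx(L, C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    double* xs = dx.slice_memptr(n);
    for (int j = 0; j < Lo; ++j) {
      const double* col = dxc.colptr((size_t)n * Lo + j);
      const int start = j * stride - pad_l;
      for (int c = 0; c < C; ++c) {
        double* xcol = xs + (size_t)c * L;
        const double* src = col + (size_t)c * k;
        for (int a = 0; a < k; ++a) {
          const int t = start + a;
          if (t >= 0 && t < L) xcol[t] += src[a];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
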