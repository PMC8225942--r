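// Fused im2col + GEMM kernels for the 3x3 "same" convolutions of the
// multi-task U-Net. Activations are (H*W*N) x C matrices; `idx` holds, for
// each of the 9 kernel offsets, the 1-based source row feeding each output
// pixel, with out-of-frame sources pointing at the sentinel row rows+1
// (implicit zeros).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat build_cols(const arma::mat& x, const IntegerMatrix& idx) {
  const arma::uword rows = idx.nrow();
  const arma::uword C = x.n_cols;
  arma::mat cols(rows, 9 * C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    for (arma::uword k = 0; k < 9; ++k) {
      double* dst = cols.colptr(c * 9 + k);
      const int* id = &idx(0, k);
      for (arma::uword p = 0; p < rows; ++p) {
        int s = id[p] - 1;
        dst[p] = (s < (int)x.n_rows) ? src[s] : 0.0;
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fw(const arma::mat& x, const IntegerMatrix& idx,
                       const arma::mat& W, const arma::vec& b) {
  arma::mat out = build_cols(x, idx) * W;
  out.each_row() += b.t();
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bw(const arma::mat& dout, const arma::mat& x,
                  const IntegerMatrix& idx, const arma::mat& W) {
  arma::mat cols = build_cols(x, idx);
  arma::mat dW = cols.t() * dout;
  arma::mat dcols = dout * W.t();
  const arma::uword rows = idx.nrow();
  const arma::uword C = x.n_cols;
  arma::mat dx(x.n_rows, C, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    double* dst = dx.colptr(c);
    for (arma::uword k = 0; k < 9; ++k) {
      const double* src = dcols.colptr(c * 9 + k);
      const int* id = &idx(0, k);
      for (arma::uword p = 0; p < rows; ++p) {
        int s = id[p] - 1;
        if (s < (int)x.n_rows) dst[s] += src[p];
      }
    }
  }
  arma::rowvec db = arma::sum(dout, 0);
  return List::create(Named("dx") = dx, Named("dW") = dW,
                      Named("db") = db.t());
}
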