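// 1-D "same" convolution (kernel 3, stride 1) as im2col + GEMM, with
// the matching backward pass.  Activations are channel-major matrices
// of dim (C, len * batch); column j = b * len + t holds the channel
// vector at time t of batch item b (0-based).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Build the (3C x len*batch) im2col matrix of A with zero padding.
static arma::mat im2col3(const arma::mat& A, int C, int len, int batch) {
  arma::mat Xcol(3 * C, (arma::uword)len * batch, arma::fill::zeros);
  for (int b = 0; b < batch; ++b) {
    const double* src0 = A.colptr((arma::uword)b * len);
    for (int t = 0; t < len; ++t) {
      double* dst = Xcol.colptr((arma::uword)b * len + t);
      for (int k = 0; k < 3; ++k) {
        int ts = t + k - 1;
        if (ts < 0 || ts >= len) continue;
        std::memcpy(dst + (arma::uword)k * C, src0 + (arma::uword)ts * C,
                    C * sizeof(double));
      }
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
arma::mat conv1d_fwd_cpp(const arma::mat& A, int C, int len, int batch,
                         const arma::mat& W, const arma::vec& b) {
  arma::mat Xcol = im2col3(A, C, len, batch);
  arma::mat out = W * Xcol;
  out.each_col() += b;
  return out;
}

// Backward pass; A is the layer *input* (the im2col matrix is rebuilt
// here rather than cached, trading a memcpy for a large allocation).
// [[Rcpp::export]]
Rcpp::List conv1d_bwd_cpp(const arma::mat& dY, const arma::mat& A,
                          const arma::mat& W, int C, int len, int batch) {
  arma::mat Xcol = im2col3(A, C, len, batch);
  arma::mat dW = dY * Xcol.t();
  arma::vec db = arma::sum(dY, 1);
  arma::mat dXcol = W.t() * dY;
  arma::mat dA(C, (arma::uword)len * batch, arma::fill::zeros);
  for (int b = 0; b < batch; ++b) {
    for (int t = 0; t < len; ++t) {
      const double* src = dXcol.colptr((arma::uword)b * len + t);
      for (int k = 0; k < 3; ++k) {
        int ts = t + k - 1;
        if (ts < 0 || ts >= len) continue;
        double* dst = dA.colptr((arma::uword)b * len + ts);
        const double* s = src + (arma::uword)k * C;
        for (int c = 0; c < C; ++c) dst[c] += s[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dA") = dA,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
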