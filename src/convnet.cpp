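// Convolution primitives for the 2D patch autoencoders.
// Layout conventions (R column-major):
//   activations x : array (H, W, C, N)
//   weights     w : array (K, K, Cin, Cout)
// Transposed convolutions are expressed in R as the adjoint of a forward
// convolution, so the three primitives below cover both layer types.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Loop order keeps the patch-row index innermost so writes walk down each
// column of the column-major `cols` matrix; out-of-range taps are skipped
// via precomputed valid ranges.
static inline arma::mat im2col(const double* x, int H, int W, int C, int N,
                               int K, int stride, int pad, int Ho, int Wo) {
  const int rows = Ho * Wo * N;
  arma::mat cols(rows, K * K * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        double* colp = cols.colptr(kh + K * (kw + K * ci));
        int ho_lo = 0;
        while (ho_lo < Ho && ho_lo * stride - pad + kh < 0) ++ho_lo;
        int ho_hi = Ho;
        while (ho_hi > ho_lo && (ho_hi - 1) * stride - pad + kh >= H) --ho_hi;
        for (int n = 0; n < N; ++n) {
          const double* xc = x + ((std::size_t)ci + (std::size_t)C * n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            double* dst = colp + (std::size_t)Ho * (wo + (std::size_t)Wo * n);
            const double* src = xc + (std::size_t)H * wi;
            int hi = ho_lo * stride - pad + kh;
            for (int ho = ho_lo; ho < ho_hi; ++ho, hi += stride) {
              dst[ho] = src[hi];
            }
          }
        }
      }
    }
  }
  return cols;
}

static inline void col2im(const arma::mat& cols, double* dx,
                          int H, int W, int C, int N,
                          int K, int stride, int pad, int Ho, int Wo) {
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < K; ++kw) {
      for (int kh = 0; kh < K; ++kh) {
        const double* colp = cols.colptr(kh + K * (kw + K * ci));
        int ho_lo = 0;
        while (ho_lo < Ho && ho_lo * stride - pad + kh < 0) ++ho_lo;
        int ho_hi = Ho;
        while (ho_hi > ho_lo && (ho_hi - 1) * stride - pad + kh >= H) --ho_hi;
        for (int n = 0; n < N; ++n) {
          double* xc = dx + ((std::size_t)ci + (std::size_t)C * n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            const double* src = colp + (std::size_t)Ho * (wo + (std::size_t)Wo * n);
            double* dst = xc + (std::size_t)H * wi;
            int hi = ho_lo * stride - pad + kh;
            for (int ho = ho_lo; ho < ho_hi; ++ho, hi += stride) {
              dst[hi] += src[ho];
            }
          }
        }
      }
    }
  }
}

// y[ho,wo,co,n] = b[co] + sum_{kh,kw,ci} x[ho*s-pad+kh, wo*s-pad+kw, ci, n] w[kh,kw,ci,co]
// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                       int stride, int pad, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int K = wd[0], Cout = wd[3];
  arma::mat cols = im2col(x.begin(), H, W, C, N, K, stride, pad, Ho, Wo);
  const arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, Cout, false, true);
  arma::mat out = cols * Wm;  // (Ho*Wo*N, Cout)
  NumericVector y((std::size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      double* yc = yp + (std::size_t)Ho * Wo * (co + (std::size_t)Cout * n);
      for (int p = 0; p < Ho * Wo; ++p)
        yc[p] = out(p + (std::size_t)Ho * Wo * n, co) + bc;
    }
  return y;
}

// gradient of conv_fwd wrt its input (also the forward pass of a transposed conv)
// [[Rcpp::export(name = ".conv_bwd_data")]]
NumericVector conv_bwd_data(NumericVector dout, NumericVector w,
                            int stride, int pad, IntegerVector xdim) {
  IntegerVector od = dout.attr("dim"), wd = w.attr("dim");
  const int Ho = od[0], Wo = od[1], Cout = od[2], N = od[3];
  const int K = wd[0], C = wd[2];
  const int H = xdim[0], Wd = xdim[1];
  arma::mat dm(Ho * Wo * N, Cout);
  const double* dp = dout.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* dc = dp + (std::size_t)Ho * Wo * (co + (std::size_t)Cout * n);
      for (int p = 0; p < Ho * Wo; ++p)
        dm(p + (std::size_t)Ho * Wo * n, co) = dc[p];
    }
  const arma::mat Wm(const_cast<double*>(w.begin()), K * K * C, Cout, false, true);
  arma::mat cols = dm * Wm.t();
  NumericVector dx((std::size_t)H * Wd * C * N);  // zero-initialised
  dx.attr("dim") = IntegerVector::create(H, Wd, C, N);
  col2im(cols, dx.begin(), H, Wd, C, N, K, stride, pad, Ho, Wo);
  return dx;
}

// gradient of conv_fwd wrt the kernel
// [[Rcpp::export(name = ".conv_bwd_w")]]
NumericVector conv_bwd_w(NumericVector x, NumericVector dout,
                         int K, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), od = dout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = od[0], Wo = od[1], Cout = od[2];
  arma::mat cols = im2col(x.begin(), H, W, C, N, K, stride, pad, Ho, Wo);
  arma::mat dm(Ho * Wo * N, Cout);
  const double* dp = dout.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* dc = dp + (std::size_t)Ho * Wo * (co + (std::size_t)Cout * n);
      for (int p = 0; p < Ho * Wo; ++p)
        dm(p + (std::size_t)Ho * Wo * n, co) = dc[p];
    }
  arma::mat dW = cols.t() * dm;  // (K*K*C, Cout)
  NumericVector out(dW.begin(), dW.end());
  out.attr("dim") = IntegerVector::create(K, K, C, Cout);
  return out;
}
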