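// im2col convolution kernels for the 4-d (H, W, C, N) tensor layout.
// Zero padding is implicit in the gather/scatter; the matrix products go
// through Armadillo's BLAS bindings.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void getDims(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// gather k x k patches (with implicit zero padding) into (k*k*C) x (Ho*Wo*N)
static arma::mat im2col(const double *x, const int dx[4], int k, int stride,
                        int pad, int Ho, int Wo) {
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  arma::mat cols(k * k * C, (size_t)Ho * Wo * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double *xn = x + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t m = (size_t)n * Ho * Wo + (size_t)wo * Ho + ho;
        double *cm = cols.colptr(m);
        int y0 = ho * stride - pad, x0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double *xc = xn + (size_t)c * H * W;
          for (int kj = 0; kj < k; ++kj) {
            int xx = x0 + kj;
            if (xx < 0 || xx >= W) { cm += k; continue; }
            const double *xcol = xc + (size_t)xx * H;
            for (int ki = 0; ki < k; ++ki) {
              int yy = y0 + ki;
              if (yy >= 0 && yy < H) cm[ki] = xcol[yy];
            }
            cm += k;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".convFwdCpp")]]
NumericVector convFwdCpp(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  int dx[4], dw[4];
  getDims(x, dx); getDims(w, dw);
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  const int Ho = (dx[0] + 2 * pad - k) / stride + 1;
  const int Wo = (dx[1] + 2 * pad - k) / stride + 1;
  const int N = dx[3];
  arma::mat cols = im2col(REAL(x), dx, k, stride, pad, Ho, Wo);
  arma::mat Wm(const_cast<double *>(REAL(w)), k * k * Cin, Cout, false);
  arma::mat out = Wm.t() * cols;                  // Cout x M
  out.each_col() += arma::vec(const_cast<double *>(REAL(b)), Cout, false);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double *yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          yp[(size_t)n * Ho * Wo * Cout + (size_t)co * Ho * Wo +
             (size_t)wo * Ho + ho] =
            out(co, (size_t)n * Ho * Wo + (size_t)wo * Ho + ho);
  return y;
}

// [[Rcpp::export(name = ".convBwdCpp")]]
List convBwdCpp(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  int dx[4], dw[4], dd[4];
  getDims(x, dx); getDims(w, dw); getDims(dy, dd);
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  const int Ho = dd[0], Wo = dd[1], N = dd[3];
  const int H = dx[0], W = dx[1];
  const size_t M = (size_t)Ho * Wo * N;

  // dy (Ho, Wo, Cout, N) -> (Cout x M)
  arma::mat dyMat(Cout, M);
  const double *dp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dyMat(co, (size_t)n * Ho * Wo + (size_t)wo * Ho + ho) =
            dp[(size_t)n * Ho * Wo * Cout + (size_t)co * Ho * Wo +
               (size_t)wo * Ho + ho];

  arma::mat cols = im2col(REAL(x), dx, k, stride, pad, Ho, Wo);
  arma::mat Wm(const_cast<double *>(REAL(w)), k * k * Cin, Cout, false);
  arma::mat dWm = cols * dyMat.t();               // (kkC x Cout)
  arma::vec db = arma::sum(dyMat, 1);
  arma::mat dcols = Wm * dyMat;                   // (kkC x M)

  NumericVector dxOut((R_xlen_t)H * W * Cin * N);
  dxOut.attr("dim") = IntegerVector::create(H, W, Cin, N);
  double *dxp = REAL(dxOut);
  for (int n = 0; n < N; ++n) {
    double *dxn = dxp + (size_t)n * H * W * Cin;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        size_t m = (size_t)n * Ho * Wo + (size_t)wo * Ho + ho;
        const double *cm = dcols.colptr(m);
        int y0 = ho * stride - pad, x0 = wo * stride - pad;
        for (int c = 0; c < Cin; ++c) {
          double *xc = dxn + (size_t)c * H * W;
          for (int kj = 0; kj < k; ++kj) {
            int xx = x0 + kj;
            if (xx < 0 || xx >= W) { cm += k; continue; }
            double *xcol = xc + (size_t)xx * H;
            for (int ki = 0; ki < k; ++ki) {
              int yy = y0 + ki;
              if (yy >= 0 && yy < H) xcol[yy] += cm[ki];
            }
            cm += k;
          }
        }
      }
    }
  }

  NumericVector dWOut(dWm.begin(), dWm.end());
  dWOut.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
  return List::create(_["dx"] = dxOut, _["dW"] = dWOut,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
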