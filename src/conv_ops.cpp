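// 1-D convolution kernels ('same' padding, stride 1, odd kernel).
//
// Arrays arrive in R's column-major (N, T, C) layout, so a time-shift by k
// is a row offset of k*N in the (N*Tp, C) matrix view of the padded buffer.
// Each kernel tap therefore reduces to one BLAS call on a strided view with
// no copying: dgemm for standard convolution, daxpy/ddot per channel for the
// depthwise part of separable convolution.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

using namespace Rcpp;

static const double ONE = 1.0, ZERO = 0.0;
static const int IONE = 1;

// pad (N,T,C) -> (N,Tp,C) with P zero timesteps on each side
static std::vector<double> pad_buffer(const double* x, int N, int T, int C,
                                      int P) {
  int Tp = T + 2 * P;
  std::vector<double> xp((size_t)N * Tp * C, 0.0);
  for (int c = 0; c < C; ++c) {
    std::copy(x + (size_t)c * N * T, x + (size_t)(c + 1) * N * T,
              xp.begin() + (size_t)c * N * Tp + (size_t)P * N);
  }
  return xp;
}

// [[Rcpp::export(name = ".sepconv_fwd")]]
List sepconv_fwd(NumericVector x, IntegerVector dims, NumericMatrix dw,
                 NumericMatrix pw, NumericVector b) {
  int N = dims[0], T = dims[1], C = dims[2];
  int K = dw.nrow(), F = pw.ncol();
  int P = (K - 1) / 2, Tp = T + 2 * P, NT = N * T, NTp = N * Tp;
  std::vector<double> xp = pad_buffer(x.begin(), N, T, C, P);
  NumericVector z((size_t)NT * C);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      double a = dw(k, c);
      F77_CALL(daxpy)(&NT, &a, xp.data() + (size_t)c * NTp + (size_t)k * N,
                      &IONE, z.begin() + (size_t)c * NT, &IONE);
    }
  }
  NumericVector y((size_t)NT * F);
  F77_CALL(dgemm)("N", "N", &NT, &F, &C, &ONE, z.begin(), &NT, pw.begin(), &C,
                  &ZERO, y.begin(), &NT FCONE FCONE);
  for (int f = 0; f < F; ++f) {
    double bf = b[f];
    double* yp = y.begin() + (size_t)f * NT;
    for (int i = 0; i < NT; ++i) yp[i] += bf;
  }
  y.attr("dim") = IntegerVector::create(N, T, F);
  return List::create(_["y"] = y, _["z"] = z);
}

// [[Rcpp::export(name = ".sepconv_bwd")]]
List sepconv_bwd(NumericVector x, IntegerVector dims, NumericMatrix dw,
                 NumericMatrix pw, NumericVector z, NumericVector dy) {
  int N = dims[0], T = dims[1], C = dims[2];
  int K = dw.nrow(), F = pw.ncol();
  int P = (K - 1) / 2, Tp = T + 2 * P, NT = N * T, NTp = N * Tp;

  NumericVector db(F);
  for (int f = 0; f < F; ++f) {
    const double* dyp = dy.begin() + (size_t)f * NT;
    double s = 0.0;
    for (int i = 0; i < NT; ++i) s += dyp[i];
    db[f] = s;
  }
  NumericMatrix dpw(C, F);
  F77_CALL(dgemm)("T", "N", &C, &F, &NT, &ONE, z.begin(), &NT, dy.begin(),
                  &NT, &ZERO, dpw.begin(), &C FCONE FCONE);
  std::vector<double> dz((size_t)NT * C);
  F77_CALL(dgemm)("N", "T", &NT, &C, &F, &ONE, dy.begin(), &NT, pw.begin(),
                  &C, &ZERO, dz.data(), &NT FCONE FCONE);

  std::vector<double> xp = pad_buffer(x.begin(), N, T, C, P);
  NumericMatrix ddw(K, C);
  std::vector<double> dxp((size_t)NTp * C, 0.0);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      ddw(k, c) = F77_CALL(ddot)(&NT,
                                 xp.data() + (size_t)c * NTp + (size_t)k * N,
                                 &IONE, dz.data() + (size_t)c * NT, &IONE);
      double a = dw(k, c);
      F77_CALL(daxpy)(&NT, &a, dz.data() + (size_t)c * NT, &IONE,
                      dxp.data() + (size_t)c * NTp + (size_t)k * N, &IONE);
    }
  }
  NumericVector dx((size_t)NT * C);
  for (int c = 0; c < C; ++c) {
    std::copy(dxp.begin() + (size_t)c * NTp + (size_t)P * N,
              dxp.begin() + (size_t)c * NTp + (size_t)P * N + NT,
              dx.begin() + (size_t)c * NT);
  }
  dx.attr("dim") = IntegerVector::create(N, T, C);
  return List::create(_["dw"] = ddw, _["pw"] = dpw, _["b"] = db, _["dx"] = dx);
}

// W is (K, C, F) column-major; extract tap k as a (C, F) matrix
static void tap_matrix(const double* W, int K, int C, int F, int k,
                       std::vector<double>& Wk) {
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      Wk[(size_t)f * C + c] = W[k + (size_t)K * c + (size_t)K * C * f];
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, IntegerVector dims, NumericVector W,
                       IntegerVector wdims, NumericVector b) {
  int N = dims[0], T = dims[1], C = dims[2];
  int K = wdims[0], F = wdims[2];
  int P = (K - 1) / 2, Tp = T + 2 * P, NT = N * T, NTp = N * Tp;
  std::vector<double> xp = pad_buffer(x.begin(), N, T, C, P);
  NumericVector y((size_t)NT * F);
  std::vector<double> Wk((size_t)C * F);
  for (int k = 0; k < K; ++k) {
    tap_matrix(W.begin(), K, C, F, k, Wk);
    double beta = (k == 0) ? 0.0 : 1.0;
    F77_CALL(dgemm)("N", "N", &NT, &F, &C, &ONE, xp.data() + (size_t)k * N,
                    &NTp, Wk.data(), &C, &beta, y.begin(), &NT FCONE FCONE);
  }
  for (int f = 0; f < F; ++f) {
    double bf = b[f];
    double* yp = y.begin() + (size_t)f * NT;
    for (int i = 0; i < NT; ++i) yp[i] += bf;
  }
  y.attr("dim") = IntegerVector::create(N, T, F);
  return y;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, IntegerVector dims, NumericVector W,
              IntegerVector wdims, NumericVector dy) {
  int N = dims[0], T = dims[1], C = dims[2];
  int K = wdims[0], F = wdims[2];
  int P = (K - 1) / 2, Tp = T + 2 * P, NT = N * T, NTp = N * Tp;
  std::vector<double> xp = pad_buffer(x.begin(), N, T, C, P);

  NumericVector db(F);
  for (int f = 0; f < F; ++f) {
    const double* dyp = dy.begin() + (size_t)f * NT;
    double s = 0.0;
    for (int i = 0; i < NT; ++i) s += dyp[i];
    db[f] = s;
  }
  NumericVector dW((size_t)K * C * F);
  std::vector<double> dWk((size_t)C * F);
  std::vector<double> Wk((size_t)C * F);
  std::vector<double> dxp((size_t)NTp * C, 0.0);
  for (int k = 0; k < K; ++k) {
    F77_CALL(dgemm)("T", "N", &C, &F, &NT, &ONE, xp.data() + (size_t)k * N,
                    &NTp, dy.begin(), &NT, &ZERO, dWk.data(), &C FCONE FCONE);
    for (int f = 0; f < F; ++f)
      for (int c = 0; c < C; ++c)
        dW[k + (size_t)K * c + (size_t)K * C * f] = dWk[(size_t)f * C + c];
    tap_matrix(W.begin(), K, C, F, k, Wk);
    F77_CALL(dgemm)("N", "T", &NT, &C, &F, &ONE, dy.begin(), &NT, Wk.data(),
                    &C, &ONE, dxp.data() + (size_t)k * N, &NTp FCONE FCONE);
  }
  NumericVector dx((size_t)NT * C);
  for (int c = 0; c < C; ++c) {
    std::copy(dxp.begin() + (size_t)c * NTp + (size_t)P * N,
              dxp.begin() + (size_t)c * NTp + (size_t)P * N + NT,
              dx.begin() + (size_t)c * NT);
  }
  dx.attr("dim") = IntegerVector::create(N, T, C);
  dW.attr("dim") = IntegerVector::create(K, C, F);
  return List::create(_["W"] = dW, _["b"] = db, _["dx"] = dx);
}
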