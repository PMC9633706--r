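#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
#include <vector>
using namespace Rcpp;

// Convolution kernels on channel-first (c, h, w, n) tensors. For a kernel
// offset (di, dj) and stride s, the spatial slice visited by the kernel is
// a (c, oh*ow*n) matrix whose columns run over (hi, wi, ni) with hi
// fastest; each column is a contiguous c-run of the input, so gathering
// and scattering are memcpy-speed. The per-offset contraction over input
// channels is a dgemm.

static void gather_slice(const double* px, int c, int h, int w, int n,
                         int di, int dj, int s, int oh, int ow,
                         double* buf) {
  R_xlen_t col = 0;
  for (int ni = 0; ni < n; ++ni)
    for (int wi = 0; wi < ow; ++wi)
      for (int hi = 0; hi < oh; ++hi, ++col) {
        const R_xlen_t src = (R_xlen_t)c *
          ((di + (R_xlen_t)s * hi) +
           (R_xlen_t)h * ((dj + (R_xlen_t)s * wi) + (R_xlen_t)w * ni));
        std::memcpy(buf + (R_xlen_t)c * col, px + src, c * sizeof(double));
      }
}

static void scatter_add_slice(double* px, int c, int h, int w, int n,
                              int di, int dj, int s, int oh, int ow,
                              const double* buf) {
  R_xlen_t col = 0;
  for (int ni = 0; ni < n; ++ni)
    for (int wi = 0; wi < ow; ++wi)
      for (int hi = 0; hi < oh; ++hi, ++col) {
        double* dst = px + (R_xlen_t)c *
          ((di + (R_xlen_t)s * hi) +
           (R_xlen_t)h * ((dj + (R_xlen_t)s * wi) + (R_xlen_t)w * ni));
        const double* src = buf + (R_xlen_t)c * col;
        for (int ci = 0; ci < c; ++ci) dst[ci] += src[ci];
      }
}

// W has dims (k, k, c, f); extract the (c, f) matrix at offset (di, dj).
static void gather_w(const double* pw, int k, int c, int f, int di, int dj,
                     double* wd) {
  for (int fi = 0; fi < f; ++fi)
    for (int ci = 0; ci < c; ++ci)
      wd[ci + (R_xlen_t)c * fi] =
        pw[di + (R_xlen_t)k * (dj + (R_xlen_t)k * (ci + (R_xlen_t)c * fi))];
}

// [[Rcpp::export]]
NumericVector conv_fwd_cf(NumericVector xp, IntegerVector dims,
                          NumericVector W, IntegerVector wdims,
                          Nullable<NumericVector> bias, int s,
                          int oh, int ow) {
  const int c = dims[0], h = dims[1], w = dims[2], n = dims[3];
  const int k = wdims[0], f = wdims[3];
  const R_xlen_t N = (R_xlen_t)oh * ow * n;
  NumericVector out((R_xlen_t)f * N);  // zero-initialized
  std::vector<double> buf((R_xlen_t)c * N), wd((R_xlen_t)c * f);
  const double one = 1.0;
  for (int dj = 0; dj < k; ++dj)
    for (int di = 0; di < k; ++di) {
      gather_slice(xp.begin(), c, h, w, n, di, dj, s, oh, ow, buf.data());
      gather_w(W.begin(), k, c, f, di, dj, wd.data());
      const int m_ = f, n_ = (int)N, k_ = c;
      F77_CALL(dgemm)("T", "N", &m_, &n_, &k_, &one, wd.data(), &k_,
                      buf.data(), &k_, &one, out.begin(), &m_
                      FCONE FCONE);
    }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    double* po = out.begin();
    for (R_xlen_t j = 0; j < N; ++j)
      for (int fi = 0; fi < f; ++fi) po[fi + (R_xlen_t)f * j] += b[fi];
  }
  out.attr("dim") = IntegerVector::create(f, oh, ow, n);
  return out;
}

// [[Rcpp::export]]
List conv_bwd_cf(NumericVector xp, IntegerVector dims, NumericVector W,
                 IntegerVector wdims, NumericVector dout, int s,
                 int oh, int ow, bool need_param_grads, bool has_bias) {
  const int c = dims[0], h = dims[1], w = dims[2], n = dims[3];
  const int k = wdims[0], f = wdims[3];
  const R_xlen_t N = (R_xlen_t)oh * ow * n;
  NumericVector dxp(xp.size());
  dxp.attr("dim") = dims;
  NumericVector dW;
  if (need_param_grads) { dW = NumericVector(W.size()); dW.attr("dim") = wdims; }
  std::vector<double> buf((R_xlen_t)c * N), wd((R_xlen_t)c * f),
    dwd((R_xlen_t)c * f), dxm((R_xlen_t)c * N);
  const double one = 1.0, zero = 0.0;
  const int m_c = c, n_N = (int)N, k_f = f, n_f = f;
  for (int dj = 0; dj < k; ++dj)
    for (int di = 0; di < k; ++di) {
      gather_w(W.begin(), k, c, f, di, dj, wd.data());
      if (need_param_grads) {
        gather_slice(xp.begin(), c, h, w, n, di, dj, s, oh, ow, buf.data());
        // dWd (c, f) = slice (c, N) x t(dout (f, N))
        F77_CALL(dgemm)("N", "T", &m_c, &n_f, &n_N, &one, buf.data(), &m_c,
                        dout.begin(), &k_f, &zero, dwd.data(), &m_c
                        FCONE FCONE);
        for (int fi = 0; fi < f; ++fi)
          for (int ci = 0; ci < c; ++ci)
            dW[di + (R_xlen_t)k * (dj + (R_xlen_t)k *
                                   (ci + (R_xlen_t)c * fi))] =
              dwd[ci + (R_xlen_t)c * fi];
      }
      // dxm (c, N) = Wd (c, f) x dout (f, N)
      F77_CALL(dgemm)("N", "N", &m_c, &n_N, &k_f, &one, wd.data(), &m_c,
                      dout.begin(), &k_f, &zero, dxm.data(), &m_c
                      FCONE FCONE);
      scatter_add_slice(dxp.begin(), c, h, w, n, di, dj, s, oh, ow,
                        dxm.data());
    }
  List res = List::create(_["dxp"] = dxp);
  if (need_param_grads) {
    res["dW"] = dW;
    if (has_bias) {
      NumericVector db(f);
      const double* pd = dout.begin();
      for (R_xlen_t j = 0; j < N; ++j)
        for (int fi = 0; fi < f; ++fi) db[fi] += pd[fi + (R_xlen_t)f * j];
      res["db"] = db;
    }
  }
  return res;
}
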