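// im2col / col2im kernels for the conv-net engine.
//
// Feature maps are column-major R arrays with dims (N, H, W, C). The
// column matrix has one row per output position, rows ordered (n, h2, w2)
// column-major, and one column per kernel tap ordered (di, dj, c) with di
// fastest — matching matrix(W, kh*kw*C, Cout) on the R side. Padding is
// implicit (zeros), so no padded copy of the input is ever materialized.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_nhwc(NumericVector x, IntegerVector dims,
                          int kh, int kw, int sh, int sw, int ph, int pw) {
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int H2 = (H + 2 * ph - kh) / sh + 1;
  const int W2 = (W + 2 * pw - kw) / sw + 1;
  const R_xlen_t rows = (R_xlen_t)N * H2 * W2;
  NumericMatrix col(rows, kh * kw * C);
  const double *xp = x.begin();
  double *cp = col.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const R_xlen_t col_idx = di + (R_xlen_t)kh * dj + (R_xlen_t)kh * kw * c;
        double *dst = cp + col_idx * rows;
        for (int j2 = 0; j2 < W2; ++j2) {
          const int wj = j2 * sw + dj - pw;
          const bool wok = (wj >= 0 && wj < W);
          for (int i2 = 0; i2 < H2; ++i2) {
            const int hi = i2 * sh + di - ph;
            double *d = dst + (R_xlen_t)N * (i2 + (R_xlen_t)H2 * j2);
            if (!wok || hi < 0 || hi >= H) {
              for (int n = 0; n < N; ++n) d[n] = 0.0;
            } else {
              const double *s = xp + (R_xlen_t)N *
                (hi + (R_xlen_t)H * (wj + (R_xlen_t)W * c));
              for (int n = 0; n < N; ++n) d[n] = s[n];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector col2im_nhwc(NumericMatrix dcol, IntegerVector dims,
                          int kh, int kw, int sh, int sw, int ph, int pw) {
  const int N = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int H2 = (H + 2 * ph - kh) / sh + 1;
  const int W2 = (W + 2 * pw - kw) / sw + 1;
  const R_xlen_t rows = (R_xlen_t)N * H2 * W2;
  NumericVector dx((R_xlen_t)N * H * W * C);
  dx.attr("dim") = dims;
  const double *cp = dcol.begin();
  double *xp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const R_xlen_t col_idx = di + (R_xlen_t)kh * dj + (R_xlen_t)kh * kw * c;
        const double *src = cp + col_idx * rows;
        for (int j2 = 0; j2 < W2; ++j2) {
          const int wj = j2 * sw + dj - pw;
          if (wj < 0 || wj >= W) continue;
          for (int i2 = 0; i2 < H2; ++i2) {
            const int hi = i2 * sh + di - ph;
            if (hi < 0 || hi >= H) continue;
            const double *s = src + (R_xlen_t)N * (i2 + (R_xlen_t)H2 * j2);
            double *d = xp + (R_xlen_t)N *
              (hi + (R_xlen_t)H * (wj + (R_xlen_t)W * c));
            for (int n = 0; n < N; ++n) d[n] += s[n];
          }
        }
      }
    }
  }
  return dx;
}
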