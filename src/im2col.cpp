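#include <Rcpp.h>
using namespace Rcpp;

// Column gather for im2col convolution: x is C x Npix, g is a list of
// per-tap column indices (1-based; an index beyond ncol(x) denotes zero
// padding). Returns (C * taps) x N with tap-major row blocks.
// [[Rcpp::export]]
NumericMatrix ws_im2col(NumericMatrix x, List g, int C) {
  const int taps = g.size();
  IntegerVector g0 = g[0];
  const int N = g0.size();
  const int ncx = x.ncol();
  const int crows = C * taps;
  NumericMatrix cols(crows, N);
  const double* xp = REAL(x);
  double* cp = REAL(cols);
  for (int t = 0; t < taps; ++t) {
    IntegerVector gt = g[t];
    const int* gp = INTEGER(gt);
    for (int j = 0; j < N; ++j) {
      const int src = gp[j] - 1;
      if (src < ncx) {
        memcpy(cp + (size_t)j * crows + (size_t)t * C,
               xp + (size_t)src * C, C * sizeof(double));
      }
    }
  }
  return cols;
}

// Scatter-add adjoint of ws_im2col.
// [[Rcpp::export]]
NumericMatrix ws_col2im(NumericMatrix dcols, List g, int C, int ncols_x) {
  const int taps = g.size();
  const int crows = dcols.nrow();
  const int N = dcols.ncol();
  NumericMatrix dX(C, ncols_x);
  const double* dp = REAL(dcols);
  double* op = REAL(dX);
  for (int t = 0; t < taps; ++t) {
    IntegerVector gt = g[t];
    const int* gp = INTEGER(gt);
    for (int j = 0; j < N; ++j) {
      const int dst = gp[j] - 1;
      if (dst < ncols_x) {
        const double* s = dp + (size_t)j * crows + (size_t)t * C;
        double* o = op + (size_t)dst * C;
        for (int c = 0; c < C; ++c) o[c] += s[c];
      }
    }
  }
  return dX;
}
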