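#include <Rcpp.h>
using namespace Rcpp;

// Circular-kernel focal statistics over a matrix raster.
//
// `offsets` is an n x 2 integer matrix of (di, dj) cell offsets defining the
// kernel (computed in R by circular_kernel()). Cells outside the grid are
// skipped (edge cells use in-grid kernel members only); NA cells are skipped;
// a neighborhood with no usable cell yields NA. Accumulation is IEEE double
// in kernel-offset order, so results are reproducible bit-for-bit by any
// implementation visiting offsets in the same order.

static inline double focal_one(const NumericMatrix &v,
                               const IntegerMatrix &off,
                               int i, int j, int stat, int nr, int nc) {
  double acc = 0.0;
  R_xlen_t cnt = 0;
  const int n = off.nrow();
  for (int k = 0; k < n; ++k) {
    const int ii = i + off(k, 0);
    const int jj = j + off(k, 1);
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
    const double x = v(ii, jj);
    if (ISNAN(x)) continue;
    acc += x;
    ++cnt;
  }
  if (cnt == 0) return NA_REAL;
  if (stat == 1) return acc / (double)cnt;
  return acc;
}

// [[Rcpp::export]]
NumericMatrix focal_apply_cpp(NumericMatrix v, IntegerMatrix offsets, int stat) {
  const int nr = v.nrow(), nc = v.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = focal_one(v, offsets, i, j, stat, nr, nc);
  return out;
}

// [[Rcpp::export]]
NumericVector focal_points_cpp(NumericMatrix v, IntegerMatrix offsets,
                               IntegerVector rows, IntegerVector cols, int stat) {
  const int nr = v.nrow(), nc = v.ncol();
  const R_xlen_t n = rows.size();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p)
    out[p] = focal_one(v, offsets, rows[p] - 1, cols[p] - 1, stat, nr, nc);
  return out;
}

// Separable 1-D convolution along rows then columns with edge
// renormalization (weights of out-of-grid taps are dropped and the
// remaining weights rescaled). Used to smooth white noise into
// spatially autocorrelated fields.
// [[Rcpp::export]]
NumericMatrix blur_separable_cpp(NumericMatrix v, NumericVector kernel) {
  const int nr = v.nrow(), nc = v.ncol();
  const int m = kernel.size();
  const int h = m / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along columns (vertical pass)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      long double acc = 0.0L, wsum = 0.0L;
      for (int k = 0; k < m; ++k) {
        const int ii = i + k - h;
        if (ii < 0 || ii >= nr) continue;
        acc += kernel[k] * v(ii, j);
        wsum += kernel[k];
      }
      tmp(i, j) = (double)(acc / wsum);
    }
  }
  // along rows (horizontal pass)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      long double acc = 0.0L, wsum = 0.0L;
      for (int k = 0; k < m; ++k) {
        const int jj = j + k - h;
        if (jj < 0 || jj >= nc) continue;
        acc += kernel[k] * tmp(i, jj);
        wsum += kernel[k];
      }
      out(i, j) = (double)(acc / wsum);
    }
  }
  return out;
}
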