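#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform, Felzenszwalb & Huttenlocher
// lower-envelope algorithm applied along columns then rows. Distances are
// between pixel centers on the integer lattice, so all squared distances are
// exact integers representable in doubles.

static const double INF = std::numeric_limits<double>::infinity();
// finite sentinel for "no seed": keeps the envelope intersections finite
static const double BIG = 1e20;

static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                  std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = "cpp_sqdist_transform")]]
NumericMatrix cpp_sqdist_transform(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass 1: down each column (distance along rows)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : BIG;
    edt1d(f, d, nr, v, z);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // pass 2: across each row
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    edt1d(f, d, nc, v, z);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

// Nearest-seed fill: every NA pixel takes the value of the Euclidean-nearest
// non-NA pixel (pixel centers); ties broken by the lowest column-major
// 0-based linear index. Expanding Chebyshev ring search: a seed in ring k is
// at squared distance >= k*k, so the scan stops once k*k exceeds the best
// squared distance found (rings at k*k == best are still scanned for ties).

//' @noRd
// [[Rcpp::export(name = "cpp_nn_fill")]]
NumericMatrix cpp_nn_fill(NumericMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out = clone(x);
  bool any_seed = false;
  for (int j = 0; j < nc && !any_seed; ++j)
    for (int i = 0; i < nr; ++i)
      if (!NumericMatrix::is_na(x(i, j))) { any_seed = true; break; }
  if (!any_seed) stop("nearest-neighbor fill: raster has no defined pixels");

  int kmax = std::max(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!NumericMatrix::is_na(x(i, j))) continue;
      double best = INF;
      long best_idx = -1;
      double best_val = NA_REAL;
      for (int k = 1; k <= kmax; ++k) {
        if ((double)k * k > best) break;
        int i0 = i - k, i1 = i + k, j0 = j - k, j1 = j + k;
        for (int jj = std::max(j0, 0); jj <= std::min(j1, nc - 1); ++jj) {
          bool edge_col = (jj == j0 || jj == j1);
          for (int ii = std::max(i0, 0); ii <= std::min(i1, nr - 1); ++ii) {
            if (!edge_col && ii != i0 && ii != i1) continue;  // ring only
            if (NumericMatrix::is_na(x(ii, jj))) continue;
            double di = ii - i, dj = jj - j;
            double sq = di * di + dj * dj;
            long idx = (long)jj * nr + ii;
            if (sq < best || (sq == best && idx < best_idx)) {
              best = sq;
              best_idx = idx;
              best_val = x(ii, jj);
            }
          }
        }
      }
      out(i, j) = best_val;
    }
  }
  return out;
}
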