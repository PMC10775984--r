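#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Row prefix sums: P[r][c+1] = sum of m(r, 0..c).  Used for O(1) row-run
// sums when accumulating circular (disc) neighbourhoods on binned maps.
static std::vector<double> row_prefix(const NumericMatrix& m) {
  int nr = m.nrow(), nc = m.ncol();
  std::vector<double> P((size_t)nr * (nc + 1), 0.0);
  for (int r = 0; r < nr; ++r) {
    double acc = 0.0;
    size_t off = (size_t)r * (nc + 1);
    for (int c = 0; c < nc; ++c) {
      acc += m(r, c);
      P[off + c + 1] = acc;
    }
  }
  return P;
}

// Sum of m over bins whose centre lies within `rad` bin-widths of (i, j)
// (Euclidean distance between bin centres, <= semantics).  Bins outside the
// matrix contribute zero, i.e. the map is implicitly zero padded.
static inline double disc_sum(const std::vector<double>& P, int nr, int nc,
                              int i, int j, double rad) {
  double s = 0.0;
  int R = (int)std::floor(rad);
  for (int dy = -R; dy <= R; ++dy) {
    int r = i + dy;
    if (r < 0 || r >= nr) continue;
    int w = (int)std::floor(std::sqrt(rad * rad - (double)dy * dy));
    int c0 = j - w; if (c0 < 0) c0 = 0;
    int c1 = j + w; if (c1 > nc - 1) c1 = nc - 1;
    if (c1 < c0) continue;
    size_t off = (size_t)r * (nc + 1);
    s += P[off + c1 + 1] - P[off + c0];
  }
  return s;
}

// Separable zero-padded convolution: columns with ky then rows with kx.
// Kernels must have odd length.
// [[Rcpp::export]]
NumericMatrix conv_sep_cpp(NumericMatrix m, NumericVector kx, NumericVector ky) {
  int nr = m.nrow(), nc = m.ncol();
  int hy = (ky.size() - 1) / 2, hx = (kx.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      int k0 = std::max(0, r - hy), k1 = std::min(nr - 1, r + hy);
      for (int k = k0; k <= k1; ++k) acc += m(k, c) * ky[k - r + hy];
      tmp(r, c) = acc;
    }
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      int k0 = std::max(0, c - hx), k1 = std::min(nc - 1, c + hx);
      for (int k = k0; k <= k1; ++k) acc += tmp(r, k) * kx[k - c + hx];
      out(r, c) = acc;
    }
  }
  return out;
}

// Adaptive map construction on pre-binned dwell/spike count maps, using
// expanding circular neighbourhoods (equivalent to convolution with
// unity-gain disc kernels, evaluated sparsely via prefix sums).
//
// mode = 1 (adaptive binning): thresholds are required position-sample
//   counts (dwell seconds / f_s); the smallest radius enclosing at least the
//   threshold is used.
// mode = 2 (adaptive smoothing): thresholds are alpha values of the
//   Skaggs-McNaughton criterion  r >= alpha / (n_p * sqrt(n_s))  with r in
//   bin-width units; n_s must be positive for the criterion to be satisfiable.
//
// thresholds must be sorted ascending (increasing strictness); all are
// resolved in one outward pass per bin.  Returns rates (NaN where no radius
// satisfies the criterion) and the 1-based index of the chosen radius
// (0 where unsatisfied).
// [[Rcpp::export]]
List adaptive_expand_cpp(NumericMatrix dwell, NumericMatrix spike,
                         NumericVector radii_bins, NumericVector thresholds,
                         double fs, int mode) {
  int nr = dwell.nrow(), nc = dwell.ncol();
  int nrad = radii_bins.size(), nthr = thresholds.size();
  std::vector<double> Pd = row_prefix(dwell), Ps = row_prefix(spike);
  NumericMatrix rates(nr * nc, nthr);
  IntegerMatrix ridx(nr * nc, nthr);
  std::fill(rates.begin(), rates.end(), NA_REAL);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int cell = i + nr * j;
      int t = 0;
      for (int k = 0; k < nrad && t < nthr; ++k) {
        double rad = radii_bins[k];
        double np = disc_sum(Pd, nr, nc, i, j, rad);
        if (mode == 1) {
          while (t < nthr && np >= thresholds[t]) {
            double ns = disc_sum(Ps, nr, nc, i, j, rad);
            rates(cell, t) = ns / (np * fs);
            ridx(cell, t) = k + 1;
            ++t;
          }
        } else {
          if (np <= 0.0) continue;
          double ns = disc_sum(Ps, nr, nc, i, j, rad);
          if (ns <= 0.0) continue;
          double crit = np * std::sqrt(ns) * rad;  // satisfied if >= alpha
          while (t < nthr && crit >= thresholds[t]) {
            rates(cell, t) = ns / (np * fs);
            ridx(cell, t) = k + 1;
            ++t;
          }
        }
      }
    }
  }
  return List::create(_["rates"] = rates, _["ridx"] = ridx);
}

// Radius search for the dwell-time (adaptive binning) criterion on the
// dwell map alone: for each bin and each ascending threshold, the smallest
// radius enclosing at least that count, plus the enclosed count there.
// [[Rcpp::export]]
List adaptive_bin_radius_cpp(NumericMatrix dwell, NumericVector radii_bins,
                             NumericVector thresholds) {
  int nr = dwell.nrow(), nc = dwell.ncol();
  int nrad = radii_bins.size(), nthr = thresholds.size();
  std::vector<double> Pd = row_prefix(dwell);
  IntegerMatrix ridx(nr * nc, nthr);
  NumericMatrix np(nr * nc, nthr);
  std::fill(np.begin(), np.end(), NA_REAL);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int cell = i + nr * j;
      int t = 0;
      for (int k = 0; k < nrad && t < nthr; ++k) {
        double cnt = disc_sum(Pd, nr, nc, i, j, radii_bins[k]);
        while (t < nthr && cnt >= thresholds[t]) {
          ridx(cell, t) = k + 1;
          np(cell, t) = cnt;
          ++t;
        }
      }
    }
  }
  return List::create(_["ridx"] = ridx, _["np"] = np);
}

// Disc sums of `m` at a per-bin radius given by a 1-based index into
// radii_bins (0 = no radius, returns NA).
// [[Rcpp::export]]
NumericVector disc_sum_at_idx_cpp(NumericMatrix m, IntegerVector ridx,
                                  NumericVector radii_bins) {
  int nr = m.nrow(), nc = m.ncol();
  std::vector<double> P = row_prefix(m);
  int n = ridx.size();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    int k = ridx[q];
    if (k <= 0) { out[q] = NA_REAL; continue; }
    int i = q % nr, j = q / nr;
    out[q] = disc_sum(P, nr, nc, i, j, radii_bins[k - 1]);
  }
  return out;
}

// TRUE for each query bin (1-based i, j) iff any positive count lies within
// `rad` bin widths.  Used for the empty-bin distance cutoff of the kernel
// estimators.
// [[Rcpp::export]]
LogicalVector disc_any_cpp(NumericMatrix counts, IntegerVector qi,
                           IntegerVector qj, double rad) {
  int nr = counts.nrow(), nc = counts.ncol();
  std::vector<double> P = row_prefix(counts);
  int n = qi.size();
  LogicalVector out(n);
  for (int q = 0; q < n; ++q)
    out[q] = disc_sum(P, nr, nc, qi[q] - 1, qj[q] - 1, rad) > 0.0;
  return out;
}

// Connected component labelling of a logical mask (4- or 8-connectivity),
// stack-based flood fill.  NA is treated as FALSE.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  int nnb = (conn == 8) ? 8 : 4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != TRUE || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int k = 0; k < nnb; ++k) {
          int ii = p.first + dy8[k], jj = p.second + dx8[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) == TRUE && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

// For each radius, the total number of ordered pairs (i, j), i != j, with
// d(i, j) <= r.  radii must be sorted ascending.
// [[Rcpp::export]]
NumericVector pair_counts_cpp(NumericVector x, NumericVector y,
                              NumericVector radii) {
  int n = x.size(), nr = radii.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  // histogram of squared distances into radius slots, then cumulated
  std::vector<double> slot(nr + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - xi, dy = y[j] - yi;
      double d2 = dx * dx + dy * dy;
      // first radius with r^2 >= d2
      int k = (int)(std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin());
      slot[k] += 2.0;  // ordered pairs
    }
  }
  NumericVector out(nr);
  double acc = 0.0;
  for (int k = 0; k < nr; ++k) { acc += slot[k]; out[k] = acc; }
  return out;
}
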