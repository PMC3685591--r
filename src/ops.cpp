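#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Rank filter (median) over a kr x kc window with edge replication:
// out-of-range neighbour indices are clamped to the border, so border
// pixels are duplicated in the window exactly as many times as they
// would be under replicate padding.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(const NumericMatrix& x, int kr, int kc) {
  const int nr = x.nrow(), nc = x.ncol();
  const int rr = kr / 2, rc = kc / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf((size_t)kr * kc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      size_t k = 0;
      for (int dj = -rc; dj <= rc; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        for (int di = -rr; di <= rr; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
          buf[k++] = x(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

static void run_minmax_1d(const double* in, double* out, int n, int r, bool maxf) {
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
    double v = in[lo];
    if (maxf) {
      for (int k = lo + 1; k <= hi; ++k) if (in[k] > v) v = in[k];
    } else {
      for (int k = lo + 1; k <= hi; ++k) if (in[k] < v) v = in[k];
    }
    out[i] = v;
  }
}

// Flat erosion (maxf = false) or dilation (maxf = true) with a
// (2*rr+1) x (2*rc+1) rectangular structuring element, computed
// separably.  Windows are clipped at the image border (equivalent to
// padding with +Inf for erosion and -Inf for dilation).
// [[Rcpp::export]]
NumericMatrix minmax_filter_cpp(const NumericMatrix& x, int rr, int rc, bool maxf) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  std::vector<double> colin(nr), colout(nr), rowin(nc), rowout(nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) colin[i] = x(i, j);
    run_minmax_1d(colin.data(), colout.data(), nr, rr, maxf);
    for (int i = 0; i < nr; ++i) tmp(i, j) = colout[i];
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) rowin[j] = tmp(i, j);
    run_minmax_1d(rowin.data(), rowout.data(), nc, rc, maxf);
    for (int j = 0; j < nc; ++j) out(i, j) = rowout[j];
  }
  return out;
}

// Connected-component labelling of a binary mask by breadth-first
// search.  Components are numbered 1..K in raster-scan (column-major)
// order of their first pixel, which makes the labelling deterministic.
// connectivity must be 4 or 8.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& x, int connectivity) {
  const int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!x(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < nnb; ++k) {
          int ii = p.first + di8[k], jj = p.second + dj8[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (x(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
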