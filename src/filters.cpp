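#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Median filter with a square window of side 2*radius+1.  Borders use
// replicate padding (indices clamped to the image), so every window has
// exactly (2r+1)^2 samples and the output is defined at every pixel.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int radius) {
  const int h = x.nrow(), w = x.ncol();
  const int side = 2 * radius + 1;
  NumericMatrix out(h, w);
  std::vector<double> win(side * side);
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      int m = 0;
      for (int dc = -radius; dc <= radius; ++dc) {
        int cc = std::min(std::max(c + dc, 0), w - 1);
        for (int dr = -radius; dr <= radius; ++dr) {
          int rr = std::min(std::max(r + dr, 0), h - 1);
          win[m++] = x(rr, cc);
        }
      }
      std::nth_element(win.begin(), win.begin() + m / 2, win.begin() + m);
      out(r, c) = win[m / 2];
    }
  }
  return out;
}

// 8-connected component labelling by breadth-first search.  Components
// are numbered 1, 2, ... in raster-scan order (rows scanned first) of
// their first-encountered pixel; background is 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Exact 1-D weighted k-means by dynamic programming over the sorted
// distinct values (divide-and-conquer speedup using monotonicity of
// the optimal split).  Returns the globally WCSS-optimal centroids in
// ascending order.  xs must be sorted strictly increasing, ws > 0.
namespace {
struct Dp1d {
  const std::vector<double> *cw, *cs, *cs2;
  const std::vector<double> *prev;
  std::vector<double> *cur;
  std::vector<int> *arg;

  double seg_cost(int l, int r) const {  // values l..r inclusive
    double W = (*cw)[r + 1] - (*cw)[l];
    double S = (*cs)[r + 1] - (*cs)[l];
    double S2 = (*cs2)[r + 1] - (*cs2)[l];
    double c = S2 - S * S / W;
    return c > 0 ? c : 0.0;
  }
  void solve(int lo, int hi, int optlo, int opthi) {
    if (lo > hi) return;
    int mid = (lo + hi) / 2;
    double best = R_PosInf;
    int bestl = optlo;
    int top = std::min(mid, opthi);
    for (int l = optlo; l <= top; ++l) {
      double v = (*prev)[l - 1] + seg_cost(l, mid);
      if (v < best) { best = v; bestl = l; }
    }
    (*cur)[mid] = best;
    (*arg)[mid] = bestl;
    solve(lo, mid - 1, optlo, bestl);
    solve(mid + 1, hi, bestl, opthi);
  }
};
}  // namespace

// [[Rcpp::export]]
NumericVector kmeans1d_dp_cpp(NumericVector xs, NumericVector ws, int k) {
  const int m = xs.size();
  if (k < 1 || k > m) stop("require 1 <= k <= number of distinct values");
  std::vector<double> cw(m + 1, 0), cs(m + 1, 0), cs2(m + 1, 0);
  for (int i = 0; i < m; ++i) {
    cw[i + 1] = cw[i] + ws[i];
    cs[i + 1] = cs[i] + ws[i] * xs[i];
    cs2[i + 1] = cs2[i] + ws[i] * xs[i] * xs[i];
  }
  std::vector<double> prev(m), cur(m);
  std::vector<std::vector<int> > args(k, std::vector<int>(m, 0));
  Dp1d dp;
  dp.cw = &cw; dp.cs = &cs; dp.cs2 = &cs2;
  for (int i = 0; i < m; ++i) prev[i] = dp.seg_cost(0, i);
  for (int j = 2; j <= k; ++j) {
    dp.prev = &prev; dp.cur = &cur; dp.arg = &args[j - 1];
    dp.solve(j - 1, m - 1, j - 1, m - 1);
    // positions < j-1 are infeasible with j clusters
    for (int i = 0; i < j - 1; ++i) cur[i] = R_PosInf;
    prev = cur;
  }
  NumericVector centroids(k);
  int r = m - 1;
  for (int j = k; j >= 1; --j) {
    int l = (j == 1) ? 0 : args[j - 1][r];
    double W = cw[r + 1] - cw[l];
    double S = cs[r + 1] - cs[l];
    centroids[j - 1] = S / W;
    r = l - 1;
  }
  return centroids;
}
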