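#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Max over arcs (i, j] of the circular two-sample statistic
// |mean(arc) - mean(complement)| / (s * sqrt(1/k + 1/(n-k))).
// s is the standard deviation of the whole segment; it is invariant under
// permutation, so it cancels in the permutation test and is applied once.
static double max_arc_stat(const std::vector<double> &x,
                           const std::vector<double> &isw, int &bi, int &bj) {
  int n = (int) x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
  double tot = S[n];
  double best = -1.0; bi = 0; bj = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      int k = j - i;
      if (k == n) continue;
      double arc = S[j] - S[i];
      double m1 = arc / k, m2 = (tot - arc) / (n - k);
      double stat = std::fabs(m1 - m2) * isw[k];
      if (stat > best) { best = stat; bi = i; bj = j; }
    }
  }
  return best; // note: not yet divided by s (constant across permutations)
}

// Best circular arc of one segment: returns (i, j, stat) with the arc
// (i, j] (0-based) maximizing the two-sample statistic.  Exposed for
// testing against an exhaustive SSE-minimizing oracle.
// [[Rcpp::export]]
List cpp_best_arc(NumericVector xr) {
  int n = xr.size();
  if (n < 2) stop("need at least 2 values");
  std::vector<double> x(xr.begin(), xr.end());
  std::vector<double> isw(n + 1, 0.0);
  for (int k = 1; k < n; ++k)
    isw[k] = 1.0 / std::sqrt(1.0 / k + 1.0 / (n - k));
  int bi, bj;
  double stat = max_arc_stat(x, isw, bi, bj);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = stat);
}

// Circular binary segmentation with permutation p-values.  Returns 0-based
// segment boundaries (excluding 0 and n): the sorted changepoint positions.
// p-values use (1 + #{perm >= obs}) / (n_perm + 1); permutations stop early
// once the count rules out p < alpha.
// [[Rcpp::export]]
IntegerVector cpp_cbs(NumericVector xr, double alpha, int n_perm, int seed) {
  int n = xr.size();
  std::vector<int> bounds;
  if (n >= 2) {
    std::mt19937 rng((uint32_t) seed);
    // LIFO stack of (start, end) half-open index ranges keeps the
    // segmentation order (and hence the RNG stream) deterministic
    std::vector<std::pair<int,int> > stack;
    stack.push_back(std::make_pair(0, n));
    const int max_exceed = (int) std::floor(alpha * (n_perm + 1));
    while (!stack.empty()) {
      std::pair<int,int> seg = stack.back(); stack.pop_back();
      int a = seg.first, b = seg.second, m = b - a;
      if (m < 2) continue;
      std::vector<double> x(xr.begin() + a, xr.begin() + b);
      double mean = 0; for (double v : x) mean += v; mean /= m;
      double ss = 0; for (double v : x) ss += (v - mean) * (v - mean);
      double s = std::sqrt(ss / std::max(1, m - 1));
      if (s <= 0) continue; // constant segment: nothing to split
      std::vector<double> isw(m + 1, 0.0);
      for (int k = 1; k < m; ++k)
        isw[k] = 1.0 / std::sqrt(1.0 / k + 1.0 / (m - k));
      int bi, bj;
      double obs = max_arc_stat(x, isw, bi, bj);
      int exceed = 0;
      std::vector<double> perm(x);
      bool reject = true;
      for (int p = 0; p < n_perm; ++p) {
        for (int i = m - 1; i > 0; --i) {
          std::uniform_int_distribution<int> u(0, i);
          std::swap(perm[i], perm[u(rng)]);
        }
        int pi, pj;
        double st = max_arc_stat(perm, isw, pi, pj);
        if (st >= obs) ++exceed;
        if (1 + exceed > max_exceed) { reject = false; break; }
      }
      if (!reject) continue;
      double pval = (1.0 + exceed) / (n_perm + 1.0);
      if (pval >= alpha) continue;
      // split into up to three children at a+bi and a+bj
      int c1 = a + bi, c2 = a + bj;
      if (c1 > a) bounds.push_back(c1);
      if (c2 < b) bounds.push_back(c2);
      // recurse on children (pushed right-to-left so the left child is
      // processed first, keeping the RNG stream deterministic)
      if (c2 < b) stack.push_back(std::make_pair(c2, b));
      if (c2 > c1) stack.push_back(std::make_pair(c1, c2));
      if (c1 > a) stack.push_back(std::make_pair(a, c1));
    }
  }
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());
  return IntegerVector(bounds.begin(), bounds.end());
}

// Greedy packing of fragments (in order) into reads: a read closes when the
// next fragment would push it past target_len.  Returns 1-based read index
// and the 0-based offset of each fragment within its read.
// [[Rcpp::export]]
List cpp_pack(IntegerVector lens, int target_len) {
  int n = lens.size();
  IntegerVector read(n), offset(n);
  int cur = 1, at = 0;
  for (int i = 0; i < n; ++i) {
    if (at > 0 && at + lens[i] > target_len) { ++cur; at = 0; }
    read[i] = cur;
    offset[i] = at;
    at += lens[i];
  }
  return List::create(_["read"] = read, _["offset"] = offset);
}
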