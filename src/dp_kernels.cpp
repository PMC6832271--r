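#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dynamic time warping with |a-b| local cost and the standard step set
// (i-1,j), (i,j-1), (i-1,j-1), boundary-anchored; returns the accumulated
// cost of the optimal warping path. O(nm) time, O(m) memory.
// [[Rcpp::export(rng = false)]]
double cpp_dtw(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty series");
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double c = std::fabs(x[0] - y[j]);
    prev[j] = (j == 0) ? c : prev[j - 1] + c;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::fabs(x[i] - y[j]);
      double best;
      if (j == 0) best = prev[0];
      else best = std::min({prev[j], cur[j - 1], prev[j - 1]});
      cur[j] = best + c;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Discrete Frechet distance (Eiter-Mannila coupling DP) on value sequences
// with |a-b| point distance: min over monotone couplings of the maximum
// pairwise distance. O(nm) time, O(m) memory.
// [[Rcpp::export(rng = false)]]
double cpp_frechet(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty series");
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double c = std::fabs(x[0] - y[j]);
    prev[j] = (j == 0) ? c : std::max(prev[j - 1], c);
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::fabs(x[i] - y[j]);
      double best;
      if (j == 0) best = prev[0];
      else best = std::min({prev[j], cur[j - 1], prev[j - 1]});
      cur[j] = std::max(best, c);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

static inline double nlog2n(double p) {
  return (p > 0.0) ? p * std::log2(p) : 0.0;
}

// Optimal column-axis partition for the maximal-information grid search.
//
// Input: points sorted by x. q gives each point's row (1..l) under a fixed
// row-axis partition; xgrp gives a non-decreasing group id such that points
// with equal x share a group (a column cut may never split a group).
//
// Points are first collapsed into clumps (maximal runs assignable to a
// single row, never splitting an x group); if there are more than chat
// clumps they are merged into at most chat superclumps of roughly equal
// mass. A dynamic program over clump boundaries then maximizes, for every
// number of columns k = 1..kmax, the mutual information between the column
// partition and the rows. Returns I(k), k = 1..kmax, in bits, monotone
// non-decreasing in k.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_mine_optimize(IntegerVector q, IntegerVector xgrp,
                                int l, int kmax, int chat) {
  const int n = q.size();
  if (n == 0) stop("no points");
  if (kmax < 1) stop("kmax must be >= 1");

  // chunks: runs of equal xgrp
  std::vector<int> chunk_start;
  chunk_start.push_back(0);
  for (int i = 1; i < n; ++i)
    if (xgrp[i] != xgrp[i - 1]) chunk_start.push_back(i);
  chunk_start.push_back(n);
  const int nchunk = (int)chunk_start.size() - 1;

  // clumps: merge consecutive pure chunks sharing one row
  std::vector<int> clump_end;  // exclusive end index of each clump
  int run_row = -2;            // row of current pure run, -1 if impure/none
  for (int c = 0; c < nchunk; ++c) {
    int s = chunk_start[c], e = chunk_start[c + 1];
    bool pure = true;
    for (int i = s + 1; i < e; ++i)
      if (q[i] != q[s]) { pure = false; break; }
    int row = pure ? q[s] : -1;
    if (row >= 0 && row == run_row) {
      clump_end.back() = e;           // extend current pure run
    } else {
      clump_end.push_back(e);
      run_row = row;
    }
    if (row < 0) run_row = -2;        // impure chunk closes any run
  }
  int m = (int)clump_end.size();

  // superclumps: cap candidate boundaries at chat by equal-mass merging
  std::vector<int> bnd;  // point-index boundaries, ascending, last == n
  if (m > chat && chat >= 1) {
    double target = (double)n / chat;
    double next = target;
    for (int j = 0; j < m; ++j) {
      if (clump_end[j] >= next || j == m - 1) {
        if (!bnd.empty() && bnd.back() == clump_end[j]) continue;
        bnd.push_back(clump_end[j]);
        next = clump_end[j] + target;
      }
    }
    if (bnd.back() != n) bnd.push_back(n);
  } else {
    bnd.assign(clump_end.begin(), clump_end.end());
  }
  m = (int)bnd.size();

  // cumulative per-row histograms at clump boundaries
  // cum[(size_t)b * l + r]: points of row r+1 among the first b clumps
  std::vector<int> cum((size_t)(m + 1) * l, 0);
  std::vector<int> tot(m + 1, 0);
  {
    int p = 0;
    for (int b = 0; b < m; ++b) {
      for (int r = 0; r < l; ++r)
        cum[(size_t)(b + 1) * l + r] = cum[(size_t)b * l + r];
      while (p < bnd[b]) {
        cum[(size_t)(b + 1) * l + (q[p] - 1)]++;
        ++p;
      }
      tot[b + 1] = bnd[b];
    }
  }

  const double nn = (double)n;
  double hq = 0.0;
  for (int r = 0; r < l; ++r)
    hq -= nlog2n(cum[(size_t)m * l + r] / nn);

  // column contribution G(s, i): -(nc/n)log2(nc/n) + sum_r (h/n)log2(h/n)
  auto G = [&](int s, int i) {
    double nc = (double)(tot[i] - tot[s]);
    double g = -nlog2n(nc / nn);
    const int *ci = &cum[(size_t)i * l];
    const int *cs = &cum[(size_t)s * l];
    for (int r = 0; r < l; ++r)
      g += nlog2n((ci[r] - cs[r]) / nn);
    return g;
  };

  const int K = std::min(kmax, m);
  std::vector<double> Jprev(m + 1, R_NegInf), Jcur(m + 1, R_NegInf);
  NumericVector I(kmax);
  for (int i = 1; i <= m; ++i) Jprev[i] = G(0, i);
  I[0] = 0.0;  // one column carries no information
  for (int t = 2; t <= K; ++t) {
    for (int i = t; i <= m; ++i) {
      double best = R_NegInf;
      for (int s = t - 1; s < i; ++s) {
        double val = Jprev[s] + G(s, i);
        if (val > best) best = val;
      }
      Jcur[i] = best;
    }
    I[t - 1] = hq + Jcur[m];
    std::swap(Jprev, Jcur);
    std::fill(Jcur.begin(), Jcur.end(), R_NegInf);
  }
  for (int t = 1; t < kmax; ++t) {
    if (t >= K) I[t] = I[K - 1];
    if (I[t] < I[t - 1]) I[t] = I[t - 1];
    if (I[t] < 0) I[t] = 0;
  }
  if (I[0] < 0) I[0] = 0;
  return I;
}
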