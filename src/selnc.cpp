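#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap Smith-Waterman with full traceback.
//
// Scoring: match > 0, mismatch < 0 applied per aligned pair; a gap of
// length L costs gap_open + L * gap_extend (BLAST convention).  'N'
// against anything (including 'N') scores as a mismatch.  Returns the
// single optimal local alignment (ties broken towards the smallest
// (i, j) end cell, then diagonal moves first in traceback), with
// 0-based half-open coordinates on query and target.
//
// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string target,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const long NEG = -1000000000L;
  const int W = m + 1;
  std::vector<long> H((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, NEG),
      F((size_t)(n + 1) * W, NEG);
  // pointers: ph 0=stop 1=diag 2=E(gap in target, consumes query)
  //           3=F(gap in query, consumes target); pe/pf 1=open 0=extend
  std::vector<uint8_t> ph((size_t)(n + 1) * W, 0), pe((size_t)(n + 1) * W, 0),
      pf((size_t)(n + 1) * W, 0);
  const long go = (long)gap_open + gap_extend, ge = gap_extend;
  long best = 0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char qa = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char tb = target[j - 1];
      size_t c = (size_t)i * W + j;
      // E: gap in target column (query char vs '-')
      long e_open = H[c - W] - go, e_ext = E[c - W] - ge;
      E[c] = e_open >= e_ext ? (pe[c] = 1, e_open) : (pe[c] = 0, e_ext);
      long f_open = H[c - 1] - go, f_ext = F[c - 1] - ge;
      F[c] = f_open >= f_ext ? (pf[c] = 1, f_open) : (pf[c] = 0, f_ext);
      long s = (qa == tb && qa != 'N') ? match : mismatch;
      long diag = H[c - W - 1] + s;
      long h = 0; uint8_t p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E[c] > h) { h = E[c]; p = 2; }
      if (F[c] > h) { h = F[c]; p = 3; }
      H[c] = h; ph[c] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0);
  // traceback
  int i = bi, j = bj, matches = 0, columns = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      uint8_t p = ph[c];
      if (p == 0) break;
      if (p == 1) {
        ++columns;
        if (query[i - 1] == target[j - 1] && query[i - 1] != 'N') ++matches;
        --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++columns;
      state = pe[c] ? 0 : 1;
      --i;
    } else {
      ++columns;
      state = pf[c] ? 0 : 2;
      --j;
    }
  }
  return List::create(
      _["score"] = (double)best,
      _["q_start"] = i, _["q_end"] = bi,
      _["t_start"] = j, _["t_end"] = bj,
      _["matches"] = matches, _["columns"] = columns);
}

// Best single-feature split by the two-group log-rank statistic.
//
// Candidate thresholds are midpoints between consecutive distinct
// values of x; a split is admissible when both children retain at
// least min_events observed events.  Returns c(threshold, stat, valid).
//
// [[Rcpp::export]]
NumericVector cpp_logrank_best_split(NumericVector x, NumericVector time,
                                     IntegerVector event, int min_events) {
  const int n = x.size();
  // distinct event times
  std::vector<double> et;
  for (int i = 0; i < n; ++i) if (event[i] == 1) et.push_back(time[i]);
  std::sort(et.begin(), et.end());
  et.erase(std::unique(et.begin(), et.end()), et.end());
  const int m = (int)et.size();
  if (m == 0 || n < 2) return NumericVector::create(NA_REAL, 0.0, 0.0);
  // r[i]: number of event times <= time[i]  (sample at risk for j < r[i])
  std::vector<int> r(n), eidx(n, -1);
  std::vector<double> nj(m, 0.0), dj(m, 0.0);
  for (int i = 0; i < n; ++i) {
    int lo = (int)(std::upper_bound(et.begin(), et.end(), time[i]) - et.begin());
    r[i] = lo;
    for (int j = 0; j < lo; ++j) nj[j] += 1.0;
    if (event[i] == 1) {
      int k = (int)(std::lower_bound(et.begin(), et.end(), time[i]) - et.begin());
      eidx[i] = k;
      dj[k] += 1.0;
    }
  }
  int d_tot = 0;
  for (int i = 0; i < n; ++i) if (event[i] == 1) ++d_tot;
  // sweep over x in ascending order
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> n1(m, 0.0), d1(m, 0.0);
  int d_left = 0;
  double best_stat = -1.0, best_thr = NA_REAL;
  int pos = 0;
  while (pos < n) {
    double xv = x[ord[pos]];
    // move all samples with this value into the left group
    while (pos < n && x[ord[pos]] == xv) {
      int i = ord[pos];
      for (int j = 0; j < r[i]; ++j) n1[j] += 1.0;
      if (eidx[i] >= 0) { d1[eidx[i]] += 1.0; ++d_left; }
      ++pos;
    }
    if (pos >= n) break; // no right group remains
    if (d_left < min_events || (d_tot - d_left) < min_events) continue;
    double U = 0.0, V = 0.0;
    for (int j = 0; j < m; ++j) {
      if (nj[j] < 2.0) continue;
      double p = n1[j] / nj[j];
      U += d1[j] - dj[j] * p;
      V += dj[j] * p * (1.0 - p) * (nj[j] - dj[j]) / (nj[j] - 1.0);
    }
    if (V > 1e-12) {
      double stat = U * U / V;
      if (stat > best_stat) {
        best_stat = stat;
        best_thr = (xv + x[ord[pos]]) / 2.0;
      }
    }
  }
  if (best_stat < 0.0) return NumericVector::create(NA_REAL, 0.0, 0.0);
  return NumericVector::create(best_thr, best_stat, 1.0);
}
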