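#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Incremental delta-location scan over one chromosome.
//
// Symbols are 1..m; in_c flags which symbols belong to the cluster C;
// csize is |C| (including cluster genes absent from this alphabet, which
// can never be covered and always count as missing).  For a fixed left
// endpoint the number of additional (non-C) distinct characters is
// non-decreasing in the right endpoint, so the inner extension stops as
// soon as it exceeds delta.

static int best_distance_scan(const int* S, int n, const LogicalVector& in_c,
                              int csize, int delta, std::vector<int>& cnt,
                              bool existence_only) {
  int best = -1;
  for (int a = 0; a < n; ++a) {
    int missing = csize, extra = 0;
    int bend = a - 1;
    for (int b = a; b < n; ++b) {
      int ch = S[b] - 1;
      bend = b;
      if (cnt[ch]++ == 0) {
        if (in_c[ch]) --missing; else ++extra;
      }
      if (extra > delta) break;
      int d = missing + extra;
      if (missing < csize && d <= delta) {
        if (best < 0 || d < best) best = d;
        if (existence_only || best == 0) {
          for (int i = a; i <= bend; ++i) cnt[S[i] - 1] = 0;
          return best;
        }
      }
    }
    for (int i = a; i <= bend; ++i) cnt[S[i] - 1] = 0;
  }
  return best;
}

// [[Rcpp::export]]
int cpp_best_distance(IntegerVector S, LogicalVector in_c, int csize,
                      int delta) {
  std::vector<int> cnt(in_c.size(), 0);
  return best_distance_scan(INTEGER(S), S.size(), in_c, csize, delta, cnt,
                            false);
}

// [[Rcpp::export]]
bool cpp_has_delta_location(IntegerVector S, LogicalVector in_c, int csize,
                            int delta) {
  std::vector<int> cnt(in_c.size(), 0);
  return best_distance_scan(INTEGER(S), S.size(), in_c, csize, delta, cnt,
                            true) >= 0;
}

// Monte-Carlo hit count: draws random strings of length n with symbol
// probabilities given by the cumulative vector cum (length m), and counts
// strings containing at least one delta-location of C.  Uses R's RNG so
// results are reproducible under set.seed().
// [[Rcpp::export]]
double cpp_empirical_hits(NumericVector cum, int n, double draws,
                          LogicalVector in_c, int csize, int delta) {
  int m = cum.size();
  std::vector<int> S(n), cnt(m, 0);
  double hits = 0;
  long nd = (long)draws;
  for (long it = 0; it < nd; ++it) {
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      int lo = 0, hi = m - 1;
      while (lo < hi) {               // first index with cum >= u
        int mid = (lo + hi) / 2;
        if (cum[mid] < u) lo = mid + 1; else hi = mid;
      }
      S[i] = lo + 1;
    }
    if (best_distance_scan(S.data(), n, in_c, csize, delta, cnt, true) >= 0)
      hits += 1;
    if ((it & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return hits;
}

// Exact probability that a random string of length n (symbol probabilities
// prob, independent positions) contains a delta-location of C, by full
// enumeration of all m^n strings.
// [[Rcpp::export]]
double cpp_exact_oracle(NumericVector prob, int n, LogicalVector in_c,
                        int csize, int delta) {
  int m = prob.size();
  double total = std::pow((double)m, (double)n);
  if (total > 1e7 + 0.5)
    stop("instance too large for exact enumeration (m^n > 1e7)");
  std::vector<int> S(n, 1), cnt(m, 0);
  double acc = 0;
  long nstr = (long)(total + 0.5);
  for (long it = 0; it < nstr; ++it) {
    double w = 1;
    for (int i = 0; i < n; ++i) w *= prob[S[i] - 1];
    if (w > 0 &&
        best_distance_scan(S.data(), n, in_c, csize, delta, cnt, true) >= 0)
      acc += w;
    // odometer increment
    for (int i = 0; i < n; ++i) {
      if (S[i] < m) { S[i]++; break; }
      S[i] = 1;
    }
    if ((it & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return acc;
}
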