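#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fisher exact two-sided p for a 2x2 table (a b / c d), summing
// hypergeometric point probabilities <= that of the observed table.
static double fisher2x2(int a, int b, int c, int d) {
  int m = a + b, n = c + d, k = a + c;
  int lo = std::max(0, k - n), hi = std::min(k, m);
  if (lo == hi) return 1.0;
  double lobs = R::dhyper(a, m, n, k, 1);
  double p = 0.0;
  const double tol = 1e-7;
  for (int x = lo; x <= hi; ++x) {
    double lx = R::dhyper(x, m, n, k, 1);
    if (lx <= lobs + tol) p += std::exp(lx);
  }
  return std::min(1.0, p);
}

// [[Rcpp::export]]
NumericVector fisher2x2_p_cpp(IntegerVector a, IntegerVector b,
                              IntegerVector c, IntegerVector d) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fisher2x2(a[i], b[i], c[i], d[i]);
  return out;
}

// Median Fisher-exact association p-value of each marker against its K
// nearest neighbors inside the same fixed-width genomic interval.
// calls: markers x individuals, 0 = HOM, 1 = HET, -1 = missing.
// ivl:   interval id per marker (same chrom + same window).
// Returns NA for markers alone in their interval or with no evaluable pair.
// [[Rcpp::export]]
NumericVector ld_median_p_cpp(IntegerMatrix calls, IntegerVector ivl, int K) {
  int nm = calls.nrow(), ni = calls.ncol();
  NumericVector out(nm, NA_REAL);

  // markers grouped by interval, assumed position-sorted within
  int i = 0;
  while (i < nm) {
    int j = i;
    while (j < nm && ivl[j] == ivl[i]) ++j;   // [i, j) same interval
    int len = j - i;
    for (int m = i; m < j; ++m) {
      if (len < 2) continue;
      std::vector<double> ps;
      ps.reserve(K);
      // expand outward from m to collect up to K nearest neighbors
      int lo = m - 1, hi = m + 1;
      while ((int)ps.size() < K && (lo >= i || hi < j)) {
        int nb;
        if (lo >= i && (hi >= j || (m - lo) <= (hi - m))) { nb = lo--; }
        else { nb = hi++; }
        int n11 = 0, n10 = 0, n01 = 0, n00 = 0;
        for (int q = 0; q < ni; ++q) {
          int x = calls(m, q), y = calls(nb, q);
          if (x < 0 || y < 0) continue;
          if (x == 1 && y == 1) ++n11;
          else if (x == 1) ++n10;
          else if (y == 1) ++n01;
          else ++n00;
        }
        int tot = n11 + n10 + n01 + n00;
        if (tot < 2) continue;                      // not evaluable
        ps.push_back(fisher2x2(n11, n10, n01, n00));
      }
      if (ps.empty()) continue;
      std::sort(ps.begin(), ps.end());
      size_t h = ps.size() / 2;
      out[m] = (ps.size() % 2 == 1) ? ps[h] : 0.5 * (ps[h - 1] + ps[h]);
    }
    i = j;
  }
  return out;
}
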