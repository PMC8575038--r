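#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Enrichment score of a weighted KS-like running sum. `w` holds the ranking
// weights |score|^exponent in ranked order (descending score); `hits` holds
// 1-based positions of the set's genes in that ranking, sorted ascending.
// The running sum increments w[h]/sum(w[hits]) at hits and decrements
// 1/(N - s) at misses; the ES is the signed maximum deviation from zero.
// Extremes can only occur just after a hit (maximum) or just before a hit
// (minimum), so only those 2s points are inspected. If all hit weights are
// zero the increments fall back to the unweighted 1/s.
static double es_kernel(const NumericVector& w, const int* hits, int s) {
  const int n = w.size();
  const double miss = (n > s) ? 1.0 / (n - s) : 0.0;
  double wsum = 0.0;
  for (int i = 0; i < s; ++i) wsum += w[hits[i] - 1];
  double maxdev = R_NegInf, mindev = R_PosInf;
  double cum = 0.0;
  for (int i = 0; i < s; ++i) {
    const int h = hits[i];
    // value just before this hit: cum so far minus all misses before h
    const double before = cum - (double)(h - 1 - i) * miss;
    const double inc = (wsum > 0.0) ? w[h - 1] / wsum : 1.0 / s;
    cum += inc;
    const double after = cum - (double)(h - 1 - i) * miss;
    if (before < mindev) mindev = before;
    if (after > maxdev) maxdev = after;
  }
  if (maxdev < 0.0) maxdev = 0.0;
  if (mindev > 0.0) mindev = 0.0;
  // a tie (within summation-order rounding) resolves to the negative
  // extreme, the convention of the reference GSEA implementations
  return (maxdev - (-mindev) > 1e-12) ? maxdev : mindev;
}

// [[Rcpp::export]]
double gsea_es(NumericVector w, IntegerVector hits) {
  std::vector<int> h(hits.begin(), hits.end());
  std::sort(h.begin(), h.end());
  if (h.empty()) return 0.0;
  return es_kernel(w, h.data(), (int)h.size());
}

// Permutation null: `n_perm` random size-`set_size` gene-position subsets,
// drawn with R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
NumericVector gsea_null_perm(NumericVector w, int set_size, int n_perm) {
  const int n = w.size();
  NumericVector out(n_perm);
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i + 1;
  std::vector<int> hits(set_size);
  for (int p = 0; p < n_perm; ++p) {
    // partial Fisher-Yates for a uniform subset without replacement
    for (int i = 0; i < set_size; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
      hits[i] = pool[i];
    }
    std::sort(hits.begin(), hits.end());
    out[p] = es_kernel(w, hits.data(), set_size);
  }
  return out;
}

// Exhaustive null: each column of `combos` is one subset of 1-based
// positions (as from utils::combn).
// [[Rcpp::export]]
NumericVector gsea_null_exhaustive(NumericVector w, IntegerMatrix combos) {
  const int s = combos.nrow(), m = combos.ncol();
  NumericVector out(m);
  std::vector<int> hits(s);
  for (int c = 0; c < m; ++c) {
    for (int i = 0; i < s; ++i) hits[i] = combos(i, c);
    std::sort(hits.begin(), hits.end());
    out[c] = es_kernel(w, hits.data(), s);
  }
  return out;
}
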