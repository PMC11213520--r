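#include <Rcpp.h>
using namespace Rcpp;

// Optimal-string-alignment (restricted Damerau-Levenshtein) distance between
// two integer sequences: substitutions, insertions, deletions and adjacent
// transpositions, with no substring edited twice.
static int osa_dist(const std::vector<int>& a, const std::vector<int>& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  // three rolling rows of the DP table
  std::vector<int> prev2(m + 1), prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int d = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), prev[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        d = std::min(d, prev2[j - 2] + 1);
      cur[j] = d;
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int osa_distance_cpp(IntegerVector a, IntegerVector b) {
  std::vector<int> va(a.begin(), a.end()), vb(b.begin(), b.end());
  return osa_dist(va, vb);
}

// Pairwise normalized OSA distance matrix: d(a, b) / max(len(a), len(b)),
// 0 for two empty sequences.
// [[Rcpp::export]]
NumericMatrix osa_distance_matrix_cpp(List seqs) {
  const int n = seqs.size();
  std::vector<std::vector<int> > s(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    s[i].assign(v.begin(), v.end());
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double denom = std::max(s[i].size(), s[j].size());
      const double d = denom > 0 ? osa_dist(s[i], s[j]) / denom : 0.0;
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
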