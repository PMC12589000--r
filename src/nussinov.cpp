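#include <Rcpp.h>
#include <vector>
#include <string>

// Base-pair maximization (Nussinov) over nested structures with a minimum
// hairpin loop. Pairs: Watson-Crick AT/TA/GC/CG, plus GT/TG wobble when
// allowed (sequences arrive T-normalized from R).
static inline bool can_pair(char a, char b, bool wobble) {
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return true;
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return true;
  if (wobble && ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')))
    return true;
  return false;
}

// [[Rcpp::export]]
int nussinov_cpp(std::string seq, int min_loop, bool wobble) {
  const int n = static_cast<int>(seq.size());
  if (n == 0) return 0;
  // dp[i][j] = max pairs in seq[i..j], stored in a flat upper triangle
  std::vector<int> dp(static_cast<size_t>(n) * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[(i + 1) * n + j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k], wobble)) continue;
        int inside = (k - i >= 2) ? dp[(i + 1) * n + (k - 1)] : 0;
        int outside = (k + 1 <= j) ? dp[(k + 1) * n + j] : 0;
        int cand = 1 + inside + outside;
        if (cand > best) best = cand;
      }
      dp[i * n + j] = best;
    }
  }
  return dp[0 * n + (n - 1)];
}
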