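#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Watson-Crick or G.U wobble pair on the DNA alphabet (U stored as T)
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Base-pair maximisation (Nussinov) with a minimum hairpin loop size:
// i and j may pair only if j - i - 1 >= min_loop. Returns the maximum
// number of pairs over all nested structures.
static int nussinov_pairs(const std::string &seq, int min_loop) {
  const int n = (int) seq.size();
  if (n < min_loop + 2) return 0;
  std::vector<std::vector<int>> dp(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[i][j - 1];                  // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (can_pair(seq[k], seq[j])) {
          int left = (k > i) ? dp[i][k - 1] : 0;
          int inside = (k + 1 <= j - 1) ? dp[k + 1][j - 1] : 0;
          int cand = left + inside + 1;
          if (cand > best) best = cand;
        }
      }
      dp[i][j] = best;
    }
  }
  return dp[0][n - 1];
}

// [[Rcpp::export]]
NumericVector nussinov_energy_cpp(CharacterVector seqs, int min_loop) {
  const int m = seqs.size();
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    if (CharacterVector::is_na(seqs[s])) { out[s] = NA_REAL; continue; }
    std::string seq = as<std::string>(seqs[s]);
    out[s] = -(double) nussinov_pairs(seq, min_loop);
  }
  return out;
}
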