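#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Base codes: 1=A, 2=C, 3=G, 4=U, anything else never pairs.
// Weights arrive pre-scaled to integers (x10) so the DP and the
// traceback compare exactly, with no floating-point ties.
static inline int pair_weight(int a, int b, int wc, int gu) {
  if ((a == 1 && b == 4) || (a == 4 && b == 1) ||
      (a == 2 && b == 3) || (a == 3 && b == 2)) return wc;
  if ((a == 3 && b == 4) || (a == 4 && b == 3)) return gu;
  return 0;
}

// Weighted Nussinov maximum-pairing fold.  dp[i][j] (1-based, j > i) is
// the best total weight on s[i..j]; recurrence either leaves i unpaired
// or pairs i with some k respecting the minimum hairpin loop.
// Traceback is deterministic: whenever pairing position i attains the
// optimum, i is paired (so the 5'-most paired position is as small as
// possible) with the largest such k — stems zip from the outside in,
// which keeps co-optimal long ladders intact — otherwise i is left
// unpaired.
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
List nussinov_fold_cpp(IntegerVector codes, int min_loop, int wc_w, int gu_w) {
  const int n = codes.size();
  if (n > 2000) stop("window too long for folding (%d nt)", n);
  std::vector<std::vector<int>> dp(n + 2, std::vector<int>(n + 2, 0));

  for (int span = min_loop + 1; span <= n - 1; ++span) {
    for (int i = 1; i + span <= n; ++i) {
      const int j = i + span;
      int best = dp[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        const int w = pair_weight(codes[i - 1], codes[k - 1], wc_w, gu_w);
        if (!w) continue;
        const int v = w + dp[i + 1][k - 1] + (k < j ? dp[k + 1][j] : 0);
        if (v > best) best = v;
      }
      dp[i][j] = best;
    }
  }

  std::vector<int> pi, pj, ptype;
  std::vector<std::pair<int, int>> work;
  if (n >= 2) work.push_back(std::make_pair(1, n));
  while (!work.empty()) {
    int i = work.back().first, j = work.back().second;
    work.pop_back();
    while (j - i > min_loop) {
      const int target = dp[i][j];
      if (target == 0) break;
      int chosen = -1, cw = 0;
      for (int k = j; k >= i + min_loop + 1; --k) {
        const int w = pair_weight(codes[i - 1], codes[k - 1], wc_w, gu_w);
        if (!w) continue;
        if (w + dp[i + 1][k - 1] + (k < j ? dp[k + 1][j] : 0) == target) {
          chosen = k; cw = w; break;
        }
      }
      if (chosen < 0) { ++i; continue; }  // i unpaired at the optimum
      pi.push_back(i);
      pj.push_back(chosen);
      ptype.push_back(cw == gu_w && cw != wc_w ? 2 : 1);
      if (chosen < j) work.push_back(std::make_pair(chosen + 1, j));
      j = chosen - 1;
      ++i;
    }
  }

  return List::create(_["weight"] = dp[1][n],
                      _["i"] = wrap(pi),
                      _["j"] = wrap(pj),
                      _["type"] = wrap(ptype));
}
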