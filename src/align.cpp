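#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Pair-state codes shared with the R side:
// 0 = M (Watson-Crick), 1 = W (G:U wobble), 2 = X (mismatch), 3 = G (gap).
// Bases are encoded A=0, C=1, G=2, U=3.

static inline int pair_state(int a, int b) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0) ||
      (a == 2 && b == 1) || (a == 1 && b == 2)) return 0;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1;
  return 2;
}

// Minimum-penalty global alignment of the miRNA (x, 5'->3') against the
// reversed target site (y). Column k of the alignment (counted from the
// miRNA 5' end) costs double when seed_lo <= k <= seed_hi. At most
// max_gaps gap columns are allowed. State (i, j, g) = i miRNA bases and
// j site bases consumed using g gaps; the column index is (i + j + g) / 2,
// so the seed weighting is well defined per DP state.
//
// Tie-breaks: smallest penalty, then fewest gaps; the traceback prefers
// gap columns late in the alignment (gaps pushed toward the miRNA 3' end).
// [[Rcpp::export(name = ".align_core")]]
List align_core(IntegerVector x, IntegerVector y,
                double cost_wobble, double cost_mismatch, double cost_gap,
                int seed_lo, int seed_hi, double seed_mult, int max_gaps) {
  const int n = x.size(), m = y.size(), G = max_gaps;
  const double INF = std::numeric_limits<double>::infinity();
  if (std::abs(n - m) > G)
    return List::create(_["feasible"] = false);

  std::vector<double> dp((size_t)(n + 1) * (m + 1) * (G + 1), INF);
  auto idx = [&](int i, int j, int g) {
    return ((size_t)i * (m + 1) + j) * (G + 1) + g;
  };
  auto colw = [&](int col) {
    return (col >= seed_lo && col <= seed_hi) ? seed_mult : 1.0;
  };
  double state_cost[3] = {0.0, cost_wobble, cost_mismatch};

  dp[idx(0, 0, 0)] = 0.0;
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      for (int g = 0; g <= G; ++g) {
        double cur = dp[idx(i, j, g)];
        if (cur == INF) continue;
        int col = (i + j + g) / 2 + 1;  // column formed by the next move
        double w = colw(col);
        if (i < n && j < m) {
          double c = cur + w * state_cost[pair_state(x[i], y[j])];
          if (c < dp[idx(i + 1, j + 1, g)]) dp[idx(i + 1, j + 1, g)] = c;
        }
        if (g < G) {
          double c = cur + w * cost_gap;
          if (i < n && c < dp[idx(i + 1, j, g + 1)]) dp[idx(i + 1, j, g + 1)] = c;
          if (j < m && c < dp[idx(i, j + 1, g + 1)]) dp[idx(i, j + 1, g + 1)] = c;
        }
      }
    }
  }

  double best = INF;
  int best_g = -1;
  for (int g = 0; g <= G; ++g) {
    double v = dp[idx(n, m, g)];
    if (v < best - 1e-9) { best = v; best_g = g; }
  }
  if (best_g < 0)
    return List::create(_["feasible"] = false);

  // Traceback; preferring gap moves places gaps at late (3') columns.
  const double TOL = 1e-9;
  std::vector<int> xcol, ycol, scol;  // reversed; -1 marks a gap symbol
  int i = n, j = m, g = best_g;
  while (i > 0 || j > 0 || g > 0) {
    int col = (i + j + g) / 2;  // column entered by the move being undone
    double w = colw(col), cur = dp[idx(i, j, g)];
    if (g > 0 && i > 0 && std::abs(dp[idx(i - 1, j, g - 1)] + w * cost_gap - cur) < TOL) {
      xcol.push_back(x[i - 1]); ycol.push_back(-1); scol.push_back(3);
      --i; --g;
    } else if (g > 0 && j > 0 && std::abs(dp[idx(i, j - 1, g - 1)] + w * cost_gap - cur) < TOL) {
      xcol.push_back(-1); ycol.push_back(y[j - 1]); scol.push_back(3);
      --j; --g;
    } else {
      int st = pair_state(x[i - 1], y[j - 1]);
      xcol.push_back(x[i - 1]); ycol.push_back(y[j - 1]); scol.push_back(st);
      --i; --j;
    }
  }
  std::reverse(xcol.begin(), xcol.end());
  std::reverse(ycol.begin(), ycol.end());
  std::reverse(scol.begin(), scol.end());

  return List::create(_["feasible"] = true,
                      _["penalty"] = best,
                      _["n_gaps"] = best_g,
                      _["x_aln"] = IntegerVector(xcol.begin(), xcol.end()),
                      _["y_aln"] = IntegerVector(ycol.begin(), ycol.end()),
                      _["states"] = IntegerVector(scol.begin(), scol.end()));
}
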