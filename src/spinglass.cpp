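#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simulated annealing for the signed spin-glass objective
//   H(s) = -sum_{i<j} M(i,j) * delta(s_i, s_j)
// where M already combines the positive/negative weight classes and their
// configuration-null expectations. Uses R's RNG (RNGScope via Rcpp
// attributes), so results are reproducible under set.seed().
// [[Rcpp::export]]
List spinglass_anneal(NumericMatrix M, int q, int n_restarts, double t0,
                      double t1, double cool, int proposals_per_temp) {
  const int n = M.nrow();
  std::vector<int> best(n, 0);
  double bestH = R_PosInf;
  for (int r = 0; r < n_restarts; ++r) {
    std::vector<int> s(n);
    for (int i = 0; i < n; ++i) {
      int c = (int)(unif_rand() * q);
      s[i] = c >= q ? q - 1 : c;
    }
    double H = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (s[i] == s[j]) H -= M(i, j);
    double runBestH = H;
    std::vector<int> runBest = s;
    for (double T = t0; T >= t1; T *= cool) {
      for (int it = 0; it < proposals_per_temp; ++it) {
        int v = (int)(unif_rand() * n);
        if (v >= n) v = n - 1;
        int cnew = (int)(unif_rand() * q);
        if (cnew >= q) cnew = q - 1;
        if (cnew == s[v]) continue;
        double dH = 0.0;
        for (int u = 0; u < n; ++u) {
          if (u == v) continue;
          if (s[u] == cnew) dH -= M(v, u);
          else if (s[u] == s[v]) dH += M(v, u);
        }
        if (dH <= 0.0 || unif_rand() < std::exp(-dH / T)) {
          s[v] = cnew;
          H += dH;
          if (H < runBestH) {
            runBestH = H;
            runBest = s;
          }
        }
      }
    }
    if (runBestH < bestH) {
      bestH = runBestH;
      best = runBest;
    }
  }
  return List::create(_["membership"] = IntegerVector(best.begin(), best.end()),
                      _["hamiltonian"] = bestH);
}
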