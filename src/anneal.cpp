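#include <Rcpp.h>
using namespace Rcpp;

// Core quality R = c' A c for node values c (zero-diagonal symmetric A),
// i.e. the ordered-pair double sum over i != j of A_ij c_i c_j.
static double core_R(const NumericMatrix& A, const std::vector<double>& c) {
  int n = A.nrow();
  double R = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += A(i, j) * c[j];
    R += c[i] * s;
  }
  return R;
}

// Metropolis annealing over permutations (pairwise position swaps)
// maximizing R.  `perm` maps position -> node (0-based); node at position k
// receives transition value C[k].  Uses R's RNG so set.seed() applies.
//
// Schedule: initial temperature = sd of dR over `n_probe` random swaps
// (floor 1e-8), geometric cooling by `cooling`, `swaps_per_temp` proposals
// per temperature, stop after `patience` temperatures without improvement
// of the best R, hard cap `max_temps`.
// [[Rcpp::export]]
List anneal_core_cpp(NumericMatrix A, NumericVector C, IntegerVector init,
                     double cooling, int swaps_per_temp, int patience,
                     int max_temps, int n_probe) {
  int n = A.nrow();
  std::vector<int> perm(n);       // position -> node
  std::vector<double> c(n);       // node -> value
  for (int k = 0; k < n; ++k) {
    perm[k] = init[k] - 1;
    c[perm[k]] = C[k];
  }
  std::vector<double> S(n, 0.0);  // S[x] = sum_y A[x,y] c[y]
  for (int x = 0; x < n; ++x) {
    double s = 0.0;
    for (int y = 0; y < n; ++y) s += A(x, y) * c[y];
    S[x] = s;
  }
  double R = core_R(A, c);
  double bestR = R;
  std::vector<int> best_perm = perm;

  // probe for initial temperature
  double sum = 0.0, sum2 = 0.0;
  for (int p = 0; p < n_probe; ++p) {
    int k1 = (int)(unif_rand() * n), k2 = (int)(unif_rand() * n);
    if (k1 == k2) { --p; continue; }
    int u = perm[k1], v = perm[k2];
    double du = C[k2] - C[k1];
    double dR = 2.0 * du * (S[u] - S[v]) - 2.0 * A(u, v) * du * du;
    sum += dR; sum2 += dR * dR;
  }
  double mean = sum / n_probe;
  double varp = sum2 / n_probe - mean * mean;
  double T = std::sqrt(varp > 0 ? varp : 0.0);
  if (T < 1e-8) T = 1e-8;

  int stale = 0;
  for (int t = 0; t < max_temps && stale < patience; ++t) {
    bool improved = false;
    for (int s = 0; s < swaps_per_temp; ++s) {
      int k1 = (int)(unif_rand() * n), k2 = (int)(unif_rand() * n);
      if (k1 == k2) continue;
      int u = perm[k1], v = perm[k2];
      double du = C[k2] - C[k1];
      if (du == 0.0) continue;
      double dR = 2.0 * du * (S[u] - S[v]) - 2.0 * A(u, v) * du * du;
      if (dR > 0 || unif_rand() < std::exp(dR / T)) {
        perm[k1] = v; perm[k2] = u;
        c[u] += du; c[v] -= du;
        for (int x = 0; x < n; ++x)
          S[x] += A(x, u) * du - A(x, v) * du;
        R += dR;
        if (R > bestR + 1e-15) {
          bestR = R;
          best_perm = perm;
          improved = true;
        }
      }
    }
    stale = improved ? 0 : stale + 1;
    T *= cooling;
  }

  // recompute bestR exactly from the best permutation (guards drift)
  std::vector<double> cb(n);
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    cb[best_perm[k]] = C[k];
    out[k] = best_perm[k] + 1;
  }
  return List::create(_["perm"] = out, _["R"] = core_R(A, cb));
}
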