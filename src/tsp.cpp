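#include <Rcpp.h>
#include <chrono>
using namespace Rcpp;

// Held-Karp dynamic programme over subsets: exact optimal closed tour.
// O(n^2 2^n) time, O(n 2^n) memory; intended for n <= 13.
// [[Rcpp::export(name = ".held_karp_cpp")]]
List held_karp_cpp(NumericMatrix D) {
  const int n = D.nrow();
  if (n < 2) return List::create(_["length"] = 0.0,
                                 _["tour"] = IntegerVector(n, 1));
  const int full = 1 << (n - 1);   // subsets of cities 1..n-1 (0 is fixed)
  std::vector<double> dp((size_t)full * (n - 1),
                         std::numeric_limits<double>::infinity());
  std::vector<int> parent((size_t)full * (n - 1), -1);
  for (int j = 0; j < n - 1; ++j)
    dp[(size_t)(1 << j) * (n - 1) + j] = D(0, j + 1);
  for (int S = 1; S < full; ++S) {
    for (int j = 0; j < n - 1; ++j) {
      if (!(S & (1 << j))) continue;
      double cur = dp[(size_t)S * (n - 1) + j];
      if (!std::isfinite(cur)) continue;
      for (int k = 0; k < n - 1; ++k) {
        if (S & (1 << k)) continue;
        int S2 = S | (1 << k);
        double cand = cur + D(j + 1, k + 1);
        size_t idx = (size_t)S2 * (n - 1) + k;
        if (cand < dp[idx]) {
          dp[idx] = cand;
          parent[idx] = j;
        }
      }
    }
  }
  double best = std::numeric_limits<double>::infinity();
  int best_j = -1;
  for (int j = 0; j < n - 1; ++j) {
    double cand = dp[(size_t)(full - 1) * (n - 1) + j] + D(j + 1, 0);
    if (cand < best) { best = cand; best_j = j; }
  }
  IntegerVector tour(n);
  int S = full - 1, j = best_j;
  for (int pos = n - 1; pos >= 1; --pos) {
    tour[pos] = j + 2;              // 1-based city index
    int pj = parent[(size_t)S * (n - 1) + j];
    S ^= (1 << j);
    j = pj;
  }
  tour[0] = 1;
  return List::create(_["length"] = best, _["tour"] = tour);
}

static inline double tour_len(const NumericMatrix& D,
                              const std::vector<int>& t) {
  double s = 0.0;
  int n = t.size();
  for (int i = 0; i < n; ++i) s += D(t[i], t[(i + 1) % n]);
  return s;
}

// Nearest-neighbour construction followed by 2-opt improvement passes,
// stopped at a local optimum or when the time budget expires.
// [[Rcpp::export(name = ".tsp_heuristic_cpp")]]
List tsp_heuristic_cpp(NumericMatrix D, double time_budget) {
  const int n = D.nrow();
  auto t0 = std::chrono::steady_clock::now();
  auto elapsed = [&]() {
    return std::chrono::duration<double>(
        std::chrono::steady_clock::now() - t0).count();
  };
  std::vector<int> tour;
  tour.reserve(n);
  std::vector<bool> seen(n, false);
  int cur = 0;
  tour.push_back(0);
  seen[0] = true;
  for (int step = 1; step < n; ++step) {
    int best = -1;
    double bd = std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j)
      if (!seen[j] && D(cur, j) < bd) { bd = D(cur, j); best = j; }
    tour.push_back(best);
    seen[best] = true;
    cur = best;
  }
  bool improved = true;
  while (improved && elapsed() < time_budget) {
    improved = false;
    for (int i = 0; i < n - 1 && elapsed() < time_budget; ++i) {
      for (int k = i + 2; k < n; ++k) {
        if (i == 0 && k == n - 1) continue;  // same edge pair
        double delta = D(tour[i], tour[k]) +
                       D(tour[i + 1], tour[(k + 1) % n]) -
                       D(tour[i], tour[i + 1]) -
                       D(tour[k], tour[(k + 1) % n]);
        if (delta < -1e-12) {
          std::reverse(tour.begin() + i + 1, tour.begin() + k + 1);
          improved = true;
        }
      }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tour[i] + 1;
  return List::create(_["length"] = tour_len(D, tour), _["tour"] = out);
}
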