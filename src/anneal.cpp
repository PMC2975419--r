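#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Metropolis core of the guilt-by-association annealer.
//
// State: one global term index per unknown protein. Energy bookkeeping is
// relative: matches on known-known edges are constant and handled by the R
// wrapper; matches of unknown u against its annotated neighbors are
// precomputed in K (n_unknown x n_terms counts); matches on
// unknown-unknown edges hold iff the two assignments are equal.
//
// Own mt19937 stream (not R's RNG) so a run is reproducible from its seed
// alone, independent of the caller's RNG state.

// [[Rcpp::export(name = ".anneal_core")]]
List anneal_core(IntegerVector init, List vocab, List unk_adj,
                 IntegerMatrix K, double t0, double alpha, int steps_per_t,
                 double t_min, int seed) {
  int nu = init.size();
  std::vector<int> assign(init.begin(), init.end());        // 0-based terms
  std::vector<std::vector<int>> voc(nu), adj(nu);
  for (int i = 0; i < nu; ++i) {
    IntegerVector v = vocab[i];
    voc[i].assign(v.begin(), v.end());
    IntegerVector a = unk_adj[i];
    adj[i].assign(a.begin(), a.end());
  }
  std::mt19937 gen(static_cast<unsigned int>(seed));
  auto runif01 = [&gen]() {
    // 53-bit uniform in [0, 1), portable across implementations
    uint64_t hi = gen() >> 5, lo = gen() >> 6;
    return (hi * 67108864.0 + lo) * (1.0 / 9007199254740992.0);
  };
  auto sample_int = [&](int n) {
    return static_cast<int>(runif01() * n) % n;
  };

  // relative energy of unknown u holding term t (negated match count)
  auto local_e = [&](int u, int t) {
    double e = -static_cast<double>(K(u, t));
    for (int v : adj[u]) if (assign[v] == t) e -= 1.0;
    return e;
  };

  double energy = 0.0;
  for (int u = 0; u < nu; ++u) {
    energy -= K(u, assign[u]);
    for (int v : adj[u]) if (v > u && assign[v] == assign[u]) energy -= 1.0;
  }
  double init_energy = energy;
  double best_energy = energy;
  std::vector<int> best = assign;

  // steps_per_t counts sweeps: proposals per temperature per unknown
  long steps = static_cast<long>(steps_per_t) * nu;
  for (double t = t0; t > t_min; t *= alpha) {
    for (long s = 0; s < steps; ++s) {
      int u = sample_int(nu);
      const std::vector<int> &vu = voc[u];
      if (vu.size() < 2) continue;
      int cand = vu[sample_int(vu.size())];
      if (cand == assign[u]) continue;
      double dE = local_e(u, cand) - local_e(u, assign[u]);
      if (dE <= 0 || runif01() < std::exp(-dE / t)) {
        assign[u] = cand;
        energy += dE;
        if (energy < best_energy) {
          best_energy = energy;
          best = assign;
        }
      }
    }
  }
  return List::create(_["assignment"] = IntegerVector(best.begin(),
                                                      best.end()),
                      _["energy"] = best_energy,
                      _["initial_energy"] = init_energy);
}
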