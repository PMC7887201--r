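// Look-ahead Monte Carlo descendant-path simulation.
//
// The per-candidate score simulates P independent descendant paths:
// rejection-sample a target-positive gamete at each remaining backcross
// step, pair it with the recurrent-parent haplotype, and at the terminal
// generation self the individual into K progeny whose recovery is scored.
// This is the hot loop of the whole package, hence C++ and a local
// counter-based RNG (splitmix64) seeded per candidate so that scores are
// independent across candidates and reproducible from an integer seed.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t seed) : state(seed) {}
  uint64_t next() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in [0, 1) with 53-bit resolution
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// One meiosis under the two-state Markov chain: start on a uniform copy,
// switch copies between loci l and l+1 with probability r[l].
void sample_gamete_buf(const int* c1, const int* c2, const double* r,
                       int L, SplitMix& rng, int* out) {
  int src = (rng.unif() < 0.5) ? 0 : 1;
  out[0] = src ? c2[0] : c1[0];
  for (int l = 1; l < L; ++l) {
    if (rng.unif() < r[l - 1]) src ^= 1;
    out[l] = src ? c2[l] : c1[l];
  }
}

struct PathOut {
  int n;       // selfed progeny that are target-homozygous AND meet threshold
  double v;    // max recovery among target-homozygous progeny (0 if none)
  bool failed; // attempt cap exhausted before finding a positive gamete
};

PathOut run_path(const std::vector<int>& start1, const std::vector<int>& start2,
                 const int* rp, const double* r, int L,
                 int steps, int K, double threshold, int attempt_cap,
                 const std::vector<int>& tg, SplitMix& rng) {
  const int Z = static_cast<int>(tg.size());
  std::vector<int> cur1(start1), cur2(start2), gam(L);
  for (int s = 0; s < steps; ++s) {
    bool ok = false;
    for (int a = 0; a < attempt_cap; ++a) {
      sample_gamete_buf(cur1.data(), cur2.data(), r, L, rng, gam.data());
      bool pos = true;
      for (int z = 0; z < Z; ++z) {
        if (!gam[tg[z]]) { pos = false; break; }
      }
      if (pos) { ok = true; break; }
    }
    if (!ok) return PathOut{0, 0.0, true};
    cur1 = gam;
    std::copy(rp, rp + L, cur2.begin());
  }
  std::vector<int> ga(L), gb(L);
  int n = 0;
  double v = 0.0;
  const double denom = 2.0 * (L - Z);
  for (int k = 0; k < K; ++k) {
    sample_gamete_buf(cur1.data(), cur2.data(), r, L, rng, ga.data());
    sample_gamete_buf(cur1.data(), cur2.data(), r, L, rng, gb.data());
    bool pos = true;
    for (int z = 0; z < Z; ++z) {
      if (!(ga[tg[z]] && gb[tg[z]])) { pos = false; break; }
    }
    if (!pos) continue;
    int tot = 0;
    for (int l = 0; l < L; ++l) tot += ga[l] + gb[l];
    double rec = 100.0 * (tot - 2 * Z) / denom;  // positives carry 2Z target alleles
    if (rec > v) v = rec;
    if (rec >= threshold) ++n;
  }
  return PathOut{n, v, false};
}

std::vector<int> targets0(const IntegerVector& targets, int L) {
  std::vector<int> tg(targets.size());
  for (int i = 0; i < targets.size(); ++i) {
    int t = targets[i] - 1;  // R side is 1-based
    if (t < 0 || t >= L) stop("target index out of range");
    tg[i] = t;
  }
  return tg;
}

} // namespace

// [[Rcpp::export]]
List cpp_lookahead_path(IntegerMatrix G, IntegerVector rp_hap, NumericVector r,
                        int steps, int K, double threshold, int attempt_cap,
                        IntegerVector targets, double seed) {
  const int L = G.nrow();
  if (rp_hap.size() != L || r.size() != L - 1) stop("dimension mismatch");
  std::vector<int> c1(L), c2(L);
  for (int l = 0; l < L; ++l) { c1[l] = G(l, 0); c2[l] = G(l, 1); }
  std::vector<int> tg = targets0(targets, L);
  SplitMix rng(static_cast<uint64_t>(seed));
  PathOut po = run_path(c1, c2, &rp_hap[0], &r[0], L, steps, K, threshold,
                        attempt_cap, tg, rng);
  return List::create(_["n"] = po.n, _["v"] = po.v, _["failed"] = po.failed);
}

// [[Rcpp::export]]
double cpp_lmc_score(IntegerMatrix G, IntegerVector rp_hap, NumericVector r,
                     int steps, int K, double threshold, int attempt_cap,
                     IntegerVector targets, int P, double seed) {
  const int L = G.nrow();
  if (rp_hap.size() != L || r.size() != L - 1) stop("dimension mismatch");
  std::vector<int> c1(L), c2(L);
  for (int l = 0; l < L; ++l) { c1[l] = G(l, 0); c2[l] = G(l, 1); }
  std::vector<int> tg = targets0(targets, L);
  SplitMix rng(static_cast<uint64_t>(seed));
  double q = 0.0;
  for (int j = 0; j < P; ++j) {
    PathOut po = run_path(c1, c2, &rp_hap[0], &r[0], L, steps, K, threshold,
                          attempt_cap, tg, rng);
    if (!po.failed && po.n > 0) {
      q += (static_cast<double>(po.n) / K) * po.v;
    }
  }
  return q / P;
}
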