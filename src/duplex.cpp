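#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex minimum free energy by nearest-neighbour dynamic
// programming.  The miRNA (5'->3') pairs antiparallel with the target site;
// internally the target is reversed so consecutive pairs advance on both
// strands.  Stacks between adjacent pairs use the 6x6 table over pair types
// (AU, UA, GC, CG, GU, UG, miRNA base first); non-adjacent pairs pay an
// affine bulge/internal-loop cost.  Stacks whose 3'-side pair sits within
// the miRNA seed (positions <= seed_end) are scaled by seed_weight.

static inline int pair_code(int a, int b) {
  // bases: A=0, C=1, G=2, U=3 ; pair types indexed as in R's PAIR_TYPES
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 3 && b == 0) return 1;  // UA
  if (a == 2 && b == 1) return 2;  // GC
  if (a == 1 && b == 2) return 3;  // CG
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

static inline bool weak_pair(int p) {
  return p == 0 || p == 1 || p == 4 || p == 5;  // AU or GU type
}

// [[Rcpp::export(name = ".duplex_dp")]]
double duplex_dp(IntegerVector mirna, IntegerVector target,
                 NumericMatrix stack, double init, double end_penalty,
                 double loop_open, double loop_extend, int max_loop,
                 double seed_weight, int seed_end) {
  const int n = mirna.size();
  const int L = target.size();
  if (n == 0 || L == 0) return R_PosInf;

  // reverse the target so pairing advances left-to-right on both strands
  std::vector<int> u(L);
  for (int k = 0; k < L; ++k) u[k] = target[L - 1 - k];

  const double INF = R_PosInf;
  std::vector<double> E(n * L, INF);
  double best = INF;

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < L; ++k) {
      int p = pair_code(mirna[i], u[k]);
      if (p < 0) continue;
      // open a new duplex at (i, k)
      double e = init + (weak_pair(p) ? end_penalty : 0.0);
      // or extend from a previous pair (i2, k2)
      int i_lo = std::max(0, i - 1 - max_loop);
      int k_lo = std::max(0, k - 1 - max_loop);
      for (int i2 = i - 1; i2 >= i_lo; --i2) {
        for (int k2 = k - 1; k2 >= k_lo; --k2) {
          double prev = E[i2 * L + k2];
          if (!R_finite(prev)) continue;
          int gi = i - i2 - 1, gk = k - k2 - 1;
          double cost;
          if (gi == 0 && gk == 0) {
            int p2 = pair_code(mirna[i2], u[k2]);
            double st = stack(p2, p);
            if (i < seed_end) st *= seed_weight;
            cost = st;
          } else {
            cost = loop_open + loop_extend * (gi + gk - 1);
          }
          if (prev + cost < e) e = prev + cost;
        }
      }
      E[i * L + k] = e;
      double closed = e + (weak_pair(p) ? end_penalty : 0.0);
      if (closed < best) best = closed;
    }
  }
  return best;
}
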