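// Minimum-free-energy intermolecular RNA duplex under a nearest-neighbor
// stacking model (Watson-Crick + GU wobble), with a linear per-unpaired-
// nucleotide cost for interior loops/bulges and a duplex initiation
// penalty. Energies in kJ/mol at 37 C. The model: a duplex is a monotone
// set of base pairs between the upstream strand (5'->3') and the reversed
// anti-SD strand; a step between consecutive pairs costs
//   min(stack energy, 0)        if the pairs are contiguous on both strands
//   loop_penalty * n_unpaired   otherwise.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double KCAL2KJ = 4.184;
static const double INF = std::numeric_limits<double>::infinity();

// pair type codes: 0 CG, 1 GC, 2 GU, 3 UG, 4 AU, 5 UA, -1 not pairable.
// x = base on strand a, y = base on (reversed) strand b. bases: A0 C1 G2 U3
static int pair_code(int x, int y) {
  if (x == 1 && y == 2) return 0;  // CG
  if (x == 2 && y == 1) return 1;  // GC
  if (x == 2 && y == 3) return 2;  // GU
  if (x == 3 && y == 2) return 3;  // UG
  if (x == 0 && y == 3) return 4;  // AU
  if (x == 3 && y == 0) return 5;  // UA
  return -1;
}

static int rev_pair(int p) {
  switch (p) { case 0: return 1; case 1: return 0; case 2: return 3;
               case 3: return 2; case 4: return 5; case 5: return 4; }
  return -1;
}

// Turner-1999 delta-G(37) stacking table, kcal/mol, rows/cols in the order
// CG GC GU UG AU UA. Entry [p][q] is the stack of outer pair p over inner
// pair q *with the inner pair read on the opposite strand* (the standard
// table layout); stack_energy() below applies the orientation convention.
static const double STACK99[6][6] = {
  {-2.40, -3.30, -2.10, -1.40, -2.10, -2.10},
  {-3.30, -3.40, -2.50, -1.50, -2.20, -2.40},
  {-2.10, -2.50,  1.30, -0.50, -1.40, -1.30},
  {-1.40, -1.50, -0.50,  0.30, -0.60, -1.00},
  {-2.10, -2.20, -1.40, -0.60, -1.10, -0.90},
  {-2.10, -2.40, -1.30, -1.00, -0.90, -1.30}
};

static const double DUPLEX_INIT_KCAL = 4.10;

// stack energy (kJ/mol) for pair p1 = (a[i], c[k]) followed 5'->3' on a by
// pair p2 = (a[i+1], c[k+1])
static double stack_energy(int p1, int p2) {
  return STACK99[p1][rev_pair(p2)] * KCAL2KJ;
}

// a, c: integer base codes (A0 C1 G2 U3); c is the anti-SD already reversed.
// Returns the duplex MFE (<= 0; 0 if no stable duplex).
// [[Rcpp::export]]
double cpp_duplex_mfe(IntegerVector a, IntegerVector c,
                      double loop_penalty = 2.1) {
  int n = a.size(), m = c.size();
  if (n == 0 || m == 0) return 0.0;
  const double init = DUPLEX_INIT_KCAL * KCAL2KJ;
  std::vector<std::vector<double>> E(n, std::vector<double>(m, INF));
  std::vector<std::vector<double>> G(n, std::vector<double>(m, INF));
  double best = INF;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      int p = pair_code(a[i], c[k]);
      if (p >= 0) {
        double e = init;  // open the duplex at this pair
        if (i > 0 && k > 0) {
          int pprev = pair_code(a[i - 1], c[k - 1]);
          if (pprev >= 0 && E[i - 1][k - 1] < INF) {
            double st = E[i - 1][k - 1] + stack_energy(pprev, p);
            if (st < e) e = st;
          }
          // loop/bulge closure from any earlier pair (zero-gap case is the
          // no-stack contiguous step, cost 0, included in G)
          if (G[i - 1][k - 1] < INF && G[i - 1][k - 1] < e) e = G[i - 1][k - 1];
        }
        E[i][k] = e;
        if (e < best) best = e;
      }
      // G[i][k] = min over (i'<=i, k'<=k) of E[i'][k'] + loop_penalty *
      //           ((i - i') + (k - k'))
      double g = E[i][k];
      if (i > 0 && G[i - 1][k] + loop_penalty < g) g = G[i - 1][k] + loop_penalty;
      if (k > 0 && G[i][k - 1] + loop_penalty < g) g = G[i][k - 1] + loop_penalty;
      G[i][k] = g;
    }
  }
  if (best >= 0.0 || best == INF) return 0.0;
  return best;
}
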