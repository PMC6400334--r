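#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Exact minimum-mismatch partition of reads into at most max_groups
// haplotype groups. The cost of a group is, summed over sites, the
// minority allele count among the member reads covering the site (the
// irreducible mismatch count against any consensus). Solved by bitmask
// subset dynamic programming; intended for small instances
// (<= ~14 reads, <= ~16 sites).
//
// reads: integer matrix, rows = reads, cols = sites, entries 0/1 or
// NA (not covered).
// [[Rcpp::export]]
int exact_phase_cost_cpp(IntegerMatrix reads, int max_groups = 4) {
  const int n = reads.nrow();
  const int s = reads.ncol();
  if (n > 20) stop("exact_phase_cost: too many reads for exhaustive search");
  const int full = (1 << n) - 1;

  // per-subset, per-site allele counts, built incrementally by low bit
  std::vector<int> cost(full + 1, 0);
  std::vector<short> c0((size_t)(full + 1) * s, 0), c1((size_t)(full + 1) * s, 0);
  for (int S = 1; S <= full; ++S) {
    int i = __builtin_ctz(S);       // lowest set bit = read index
    int T = S & (S - 1);
    int c = 0;
    for (int k = 0; k < s; ++k) {
      short a0 = c0[(size_t)T * s + k], a1 = c1[(size_t)T * s + k];
      int obs = reads(i, k);
      if (obs != NA_INTEGER) {
        if (obs == 0) ++a0; else ++a1;
      }
      c0[(size_t)S * s + k] = a0;
      c1[(size_t)S * s + k] = a1;
      c += (a0 < a1 ? a0 : a1);
    }
    cost[S] = c;
  }

  std::vector<int> f(cost.begin(), cost.end());   // k = 1
  std::vector<int> g(full + 1);
  int best = f[full];
  for (int k = 2; k <= max_groups; ++k) {
    g[0] = 0;
    for (int S = 1; S <= full; ++S) {
      int b = f[S];                 // leave one group empty
      // iterate proper non-empty submasks containing the lowest bit of S
      // (fixing the lowest bit halves the enumeration and loses nothing)
      int low = S & (-S);
      for (int T = S; T; T = (T - 1) & S) {
        if (!(T & low)) continue;
        if (T == S) continue;
        int c = cost[T] + f[S ^ T];
        if (c < b) b = c;
      }
      g[S] = b;
    }
    f.swap(g);
    if (f[full] < best) best = f[full];
  }
  return best;
}
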