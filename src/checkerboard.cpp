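#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard (double-edge) swap chain on a binary incidence matrix.
// Picks two links (a1,p1), (a2,p2) with distinct rows and columns and with
// (a1,p2), (a2,p1) absent, and rewires to the latter pair; repeats until
// n_swaps are accepted or max_attempts proposals are exhausted. Degrees are
// preserved exactly. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_checkerboard(IntegerMatrix inc, int n_swaps,
                               double max_attempts) {
  IntegerMatrix m = clone(inc);
  int A = m.nrow(), P = m.ncol();
  int L = 0;
  for (int j = 0; j < P; ++j)
    for (int i = 0; i < A; ++i)
      if (m(i, j) == 1) ++L;
  if (L < 2) {
    m.attr("accepted") = 0;
    return m;
  }
  std::vector<int> ea(L), ep(L);
  int e = 0;
  for (int j = 0; j < P; ++j)
    for (int i = 0; i < A; ++i)
      if (m(i, j) == 1) { ea[e] = i; ep[e] = j; ++e; }

  int accepted = 0;
  double attempts = 0;
  while (accepted < n_swaps && attempts < max_attempts) {
    attempts += 1;
    int i = (int)(unif_rand() * L);
    int j = (int)(unif_rand() * L);
    if (i == j) continue;
    int a1 = ea[i], p1 = ep[i], a2 = ea[j], p2 = ep[j];
    if (a1 == a2 || p1 == p2) continue;
    if (m(a1, p2) == 1 || m(a2, p1) == 1) continue;
    m(a1, p1) = 0; m(a2, p2) = 0;
    m(a1, p2) = 1; m(a2, p1) = 1;
    ep[i] = p2; ep[j] = p1;
    ++accepted;
  }
  m.attr("accepted") = accepted;
  return m;
}
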