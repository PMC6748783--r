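#include <Rcpp.h>
using namespace Rcpp;

// Two-sided exact p-values, "sum of outcome probabilities <= observed"
// convention, for families whose log pmf on support s = 0..tot decomposes
// as tabA[s] + tabB[tot - s] + lconst (conditional-NB, binomial and
// hypergeometric all do).  Support is scanned on [lo, hi]; mass outside
// the window is counted as extreme (callers choose windows wide enough
// that this mass is negligible and entirely in the tails).
// [[Rcpp::export]]
NumericVector cpp_exact_two_sided(IntegerVector obs, IntegerVector tot,
                                  IntegerVector lo, IntegerVector hi,
                                  NumericVector tabA, NumericVector tabB,
                                  NumericVector lconst) {
  const int G = obs.size();
  NumericVector p(G);
  for (int g = 0; g < G; ++g) {
    const int t = tot[g];
    const double lc = lconst[g];
    const double lp_obs = tabA[obs[g]] + tabB[t - obs[g]] + lc + 1e-7;
    double mass = 0.0, extreme = 0.0;
    for (int s = lo[g]; s <= hi[g]; ++s) {
      const double lp = tabA[s] + tabB[t - s] + lc;
      const double pm = std::exp(lp);
      mass += pm;
      if (lp <= lp_obs) extreme += pm;
    }
    double out = extreme + std::max(0.0, 1.0 - mass);
    if (out > 1.0) out = 1.0;
    if (out < DBL_MIN) out = DBL_MIN;
    p[g] = out;
  }
  return p;
}
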