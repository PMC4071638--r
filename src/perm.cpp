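#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo permutation sampling of the difference-of-means statistic.
//
// pooled:   concatenated values (first population first)
// nA:       size of the first population
// observed: observed statistic mean(A) - mean(B) (absolute value when
//           twoSided)
// Sampling runs in batches; after minPerms the loop stops when the
// relative change of the running p-estimate (b+1)/(m+1) over the last
// batch drops below stopTol, or when maxPerms is reached.  Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
List perm_mc(NumericVector pooled, int nA, double observed,
             int minPerms, int batch, double stopTol, int maxPerms,
             bool twoSided) {
  const int n = pooled.size();
  const int nB = n - nA;
  if (nA <= 0 || nB <= 0) stop("both populations must be non-empty");
  std::vector<double> v(pooled.begin(), pooled.end());
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += v[i];

  const double eps = 1e-12;
  const double obs = twoSided ? std::fabs(observed) : observed;
  long b = 0, m = 0;
  double pPrev = -1.0;
  long target = minPerms;
  if (maxPerms < minPerms) maxPerms = minPerms;

  while (true) {
    for (; m < target; ++m) {
      // partial Fisher-Yates: the first nA entries become a uniformly
      // random subset (v stays a permutation of pooled across draws)
      double sA = 0.0;
      for (int i = 0; i < nA; ++i) {
        int j = i + (int)(unif_rand() * (n - i));
        if (j >= n) j = n - 1;
        std::swap(v[i], v[j]);
        sA += v[i];
      }
      double stat = sA / nA - (total - sA) / nB;
      if (twoSided) stat = std::fabs(stat);
      if (stat >= obs - eps) ++b;
    }
    double p = (b + 1.0) / (m + 1.0);
    bool stable = (pPrev > 0.0) &&
      (std::fabs(p - pPrev) / pPrev < stopTol);
    if (stable || m >= maxPerms) break;
    pPrev = p;
    target = std::min((long)maxPerms, m + (long)batch);
  }
  return List::create(_["b"] = (double)b, _["m"] = (double)m);
}
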