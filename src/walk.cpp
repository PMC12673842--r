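#include <Rcpp.h>
using namespace Rcpp;

// Running sum of the enrichment walk with plain double accumulation
// (each partial sum rounded to double, unlike base cumsum's extended
// precision), so the profile is reproducible step by step in R.
// [[Rcpp::export(name = ".walkRunningSum")]]
NumericVector walkRunningSum(NumericVector inc) {
  int n = inc.size();
  NumericVector rs(n);
  double cur = 0.0;
  for (int i = 0; i < n; ++i) {
    cur += inc[i];
    rs[i] = cur;
  }
  return rs;
}

// Enrichment score for one permuted member set, given sorted 1-based hit
// positions and the per-position weights |stat|^p.  The hit-weight total
// uses a long double accumulator (matching base R's sum()) and the walk
// uses double accumulation (matching walkRunningSum), so a permuted set
// equal to the observed one yields a bit-identical score.
// [[Rcpp::export(name = ".walkEsFromHits")]]
double walkEsFromHits(IntegerVector pos, NumericVector w, int n) {
  int k = pos.size();
  long double nrAcc = 0.0;
  for (int j = 0; j < k; ++j)
    nrAcc += w[pos[j] - 1];
  double nr = (double)nrAcc;
  double miss = -1.0 / (double)(n - k);
  double cur = 0.0, best = 0.0, bestAbs = -1.0;
  int j = 0;
  for (int i = 1; i <= n; ++i) {
    if (j < k && pos[j] == i) {
      cur += w[i - 1] / nr;
      ++j;
    } else {
      cur += miss;
    }
    double a = fabs(cur);
    if (a > bestAbs) {
      bestAbs = a;
      best = cur;
    }
  }
  return best;
}
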