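// Weighted circular binary segmentation core.
//
// A candidate change is an arc (i, j] of the circularized bin vector; the
// statistic is a weighted two-sample t comparing the arc against its
// complement, with weighted means, pooled weighted residual variance and
// n - 2 degrees of freedom (reduces to the classical pooled t at unit
// weights). Arcs that wrap are complements of non-wrapping arcs and give
// the same |T|, so enumerating 0 <= i < j <= n covers every split.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct MaxArc {
  int i, j;
  double T;
};

// max |T| over arcs with min_len <= (j - i) <= n - min_len;
// ties keep the smallest i, then smallest j
MaxArc max_arc_stat(const std::vector<double>& v, const std::vector<double>& w,
                    int min_len) {
  const int n = (int)v.size();
  std::vector<double> Sw(n + 1, 0.0), Swv(n + 1, 0.0), Swv2(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    Sw[k + 1] = Sw[k] + w[k];
    Swv[k + 1] = Swv[k] + w[k] * v[k];
    Swv2[k + 1] = Swv2[k] + w[k] * v[k] * v[k];
  }
  const double Wtot = Sw[n], Vtot = Swv[n], V2tot = Swv2[n];
  const double df = n > 2 ? (double)(n - 2) : 1.0;
  MaxArc best = {0, std::min(n, std::max(min_len, 1)), 0.0};
  const int lmin = std::max(min_len, 1), lmax = n - std::max(min_len, 1);
  if (lmax < lmin) return best;
  for (int i = 0; i < n; ++i) {
    const int jlo = i + lmin, jhi = std::min(n, i + lmax);
    for (int j = jlo; j <= jhi; ++j) {
      const double WA = Sw[j] - Sw[i];
      const double WB = Wtot - WA;
      if (WA <= 0.0 || WB <= 0.0) continue;
      const double SA = Swv[j] - Swv[i];
      const double SB = Vtot - SA;
      const double mA = SA / WA, mB = SB / WB;
      const double ssA = (Swv2[j] - Swv2[i]) - WA * mA * mA;
      const double ssB = (V2tot - (Swv2[j] - Swv2[i])) - WB * mB * mB;
      double sigma2 = (ssA + ssB) / df;
      if (sigma2 < 0.0) sigma2 = 0.0;
      double denom = sigma2 * (1.0 / WA + 1.0 / WB);
      if (denom < 1e-300) denom = 1e-300;
      const double T = std::fabs(mA - mB) / std::sqrt(denom);
      if (T > best.T + 1e-12) {
        best.i = i;
        best.j = j;
        best.T = T;
      }
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
List cbs_max_stat_cpp(NumericVector values, NumericVector weights, int min_len) {
  const int n = values.size();
  if (n < 2) stop("cbs_max_stat: need at least 2 values");
  if (weights.size() != n) stop("cbs_max_stat: weight length mismatch");
  std::vector<double> v(values.begin(), values.end());
  std::vector<double> w(weights.begin(), weights.end());
  MaxArc best = max_arc_stat(v, w, min_len);
  return List::create(_["i"] = best.i, _["j"] = best.j, _["T"] = best.T);
}

// Permutation reference distribution of the max arc statistic. Values and
// weights are shuffled jointly (pairs kept together) with R's RNG, so
// set.seed() in R makes the count reproducible. If early_stop > 0 the loop
// exits once the exceedance count reaches it (used by segment() to decide
// p >= alpha without finishing the loop; the decision is unchanged).
// [[Rcpp::export]]
List cbs_perm_count_cpp(NumericVector values, NumericVector weights,
                        double T_obs, int n_perm, int min_len, int early_stop) {
  const int n = values.size();
  std::vector<double> v(values.begin(), values.end());
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<int> idx(n);
  int count = 0, done = 0;
  GetRNGstate();
  for (int p = 0; p < n_perm; ++p) {
    for (int k = 0; k < n; ++k) idx[k] = k;
    // Fisher-Yates with R uniforms
    for (int k = n - 1; k > 0; --k) {
      int r = (int)std::floor(unif_rand() * (k + 1));
      if (r > k) r = k;
      std::swap(idx[k], idx[r]);
    }
    std::vector<double> pv(n), pw(n);
    for (int k = 0; k < n; ++k) {
      pv[k] = v[idx[k]];
      pw[k] = w[idx[k]];
    }
    MaxArc b = max_arc_stat(pv, pw, min_len);
    ++done;
    if (b.T >= T_obs - 1e-12) ++count;
    if (early_stop > 0 && count >= early_stop) break;
  }
  PutRNGstate();
  return List::create(_["count"] = count, _["done"] = done);
}
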