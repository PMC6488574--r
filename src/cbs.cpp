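#include <Rcpp.h>
using namespace Rcpp;

// Max standardized arc statistic over all circular arcs (i, j], 0 <= i < j <= n,
// with 1 <= j - i <= n - 1. The statistic compares the arc mean with the mean
// of its complement, standardized by the overall sd:
//   Z_ij = (mean_in - mean_out) / (s * sqrt(1/k + 1/(n-k))).
// Returns max |Z| and the maximizing boundaries.
static double scan_stat(const std::vector<double>& S, int n, double s,
                        int* bi, int* bj) {
  double total = S[n];
  double best = -1.0;
  int besti = 0, bestj = n;
  for (int k = 1; k <= n - 1; ++k) {
    double denom = s * std::sqrt(1.0 / k + 1.0 / (n - k));
    for (int i = 0; i + k <= n; ++i) {
      int j = i + k;
      double arc = S[j] - S[i];
      double z = std::fabs(arc / k - (total - arc) / (n - k)) / denom;
      if (z > best) { best = z; besti = i; bestj = j; }
    }
  }
  if (bi) *bi = besti;
  if (bj) *bj = bestj;
  return best;
}

static void prefix_sums(const std::vector<double>& x, std::vector<double>& S) {
  S[0] = 0.0;
  for (size_t i = 0; i < x.size(); ++i) S[i + 1] = S[i] + x[i];
}

// [[Rcpp::export(name = ".cbs_scan_cpp")]]
List cbs_scan_cpp(NumericVector x) {
  int n = x.size();
  if (n < 2) stop("series must have length >= 2");
  std::vector<double> v(x.begin(), x.end());
  double mean = 0.0, ss = 0.0;
  for (double xi : v) mean += xi;
  mean /= n;
  for (double xi : v) ss += (xi - mean) * (xi - mean);
  double s = std::sqrt(ss / (n - 1));
  if (s <= 0.0)
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n, _["sd"] = 0.0);
  std::vector<double> S(n + 1);
  prefix_sums(v, S);
  int bi, bj;
  double stat = scan_stat(S, n, s, &bi, &bj);
  return List::create(_["stat"] = stat, _["i"] = bi, _["j"] = bj, _["sd"] = s);
}

// Permutation exceedance count for the max arc statistic. Shuffles x with
// Fisher-Yates driven by R's RNG (so set.seed() governs it), recomputes the
// max statistic, and counts permutations reaching `stat`. Stops early once
// `stop_count` exceedances are seen (the split can no longer be significant).
// [[Rcpp::export(name = ".cbs_perm_count_cpp")]]
List cbs_perm_count_cpp(NumericVector x, double stat, int nperm,
                        int stop_count) {
  int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  double mean = 0.0, ss = 0.0;
  for (double xi : v) mean += xi;
  mean /= n;
  for (double xi : v) ss += (xi - mean) * (xi - mean);
  double s = std::sqrt(ss / (n - 1)); // permutation-invariant
  std::vector<double> S(n + 1);
  double thresh = stat * (1.0 - 1e-12);
  int count = 0, done = 0;
  for (int b = 0; b < nperm; ++b) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(v[i], v[j]);
    }
    prefix_sums(v, S);
    double st = scan_stat(S, n, s, nullptr, nullptr);
    if (st >= thresh) ++count;
    ++done;
    if (count >= stop_count) break;
  }
  return List::create(_["count"] = count, _["nperm_done"] = done);
}
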