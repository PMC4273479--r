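#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Circular binary segmentation kernels.
//
// For a segment x[0..n-1] the circular max statistic scans all boundary
// pairs 0 <= i < j <= n whose arc length l = j - i satisfies
// min_width <= l <= n - min_width.  The mean-shift statistic for the arc
// (i, j] against its complement is
//   U(i, j) = |S_j - S_i - l * xbar| / sqrt(l * (1 - l / n))
// which equals |mean_arc - mean_rest| * sqrt(l (n - l) / n) up to the
// (permutation-invariant) global scale.  Only U matters for both the argmax
// and permutation exceedance counts; the reported t divides by the global
// sample sd.  Arcs longer than n/2 are distinct partitions (their short
// complement wraps around), so the scan covers every admissible length.

static double max_stat_scan(const double* s, int n, double xbar, int min_width,
                            int* best_i, int* best_j) {
  double best = -1.0;
  int bi = -1, bj = -1;
  int lmax = n - std::max(min_width, 1);
  for (int l = std::max(min_width, 1); l <= lmax; ++l) {
    double denom = std::sqrt((double)l * (1.0 - (double)l / n));
    double shift = l * xbar;
    for (int i = 0; i + l <= n; ++i) {
      double d = std::fabs(s[i + l] - s[i] - shift) / denom;
      if (d > best) {
        best = d;
        bi = i;
        bj = i + l;
      }
    }
  }
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  return best;
}

// true as soon as some arc reaches `threshold` (early break per permutation)
static bool exceeds_scan(const double* s, int n, double xbar, int min_width,
                         double threshold) {
  int lmax = n - std::max(min_width, 1);
  for (int l = std::max(min_width, 1); l <= lmax; ++l) {
    double lim = threshold * std::sqrt((double)l * (1.0 - (double)l / n));
    double shift = l * xbar;
    for (int i = 0; i + l <= n; ++i) {
      double d = s[i + l] - s[i] - shift;
      if (d >= lim || -d >= lim) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cbs_max_stat_cpp(NumericVector x, int min_width) {
  int n = x.size();
  std::vector<double> s(n + 1, 0.0);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    total += x[i];
    s[i + 1] = total;
  }
  double xbar = total / n;
  int bi, bj;
  double u = max_stat_scan(s.data(), n, xbar, min_width, &bi, &bj);
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - xbar) * (x[i] - xbar);
  double sd = n > 1 ? std::sqrt(ss / (n - 1)) : 0.0;
  double t = (sd > 0 && u >= 0) ? u / sd : 0.0;
  return List::create(_["u"] = u, _["t"] = t, _["i"] = bi, _["j"] = bj,
                      _["sd"] = sd);
}

// Permutation p-value of the observed max statistic with sequential early
// stopping.  Permutations run in blocks; the test stops "not significant"
// as soon as exceedances >= ceil(alpha * n_perm) (the final p-value could
// not fall below alpha), and stops "significant" at a block boundary when
// observing so few exceedances is already very unlikely (< stop_conf) under
// a true exceedance rate of alpha.  Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List cbs_perm_pvalue_cpp(NumericVector x, double u_obs, int n_perm,
                         double alpha, int min_width, int block = 100,
                         double stop_conf = 1e-3) {
  int n = x.size();
  std::vector<double> perm(x.begin(), x.end());
  std::vector<double> s(n + 1, 0.0);
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += x[i];
  double xbar = total / n;

  int max_exceed = (int)std::ceil(alpha * n_perm);
  if (max_exceed < 1) max_exceed = 1;
  int exceed = 0, done = 0;
  bool decided = false;
  bool significant = false;

  while (done < n_perm && !decided) {
    int stop_at = std::min(done + block, n_perm);
    for (; done < stop_at; ++done) {
      // Fisher-Yates shuffle with R's RNG
      for (int i = n - 1; i > 0; --i) {
        int k = (int)(unif_rand() * (i + 1));
        if (k > i) k = i;
        std::swap(perm[i], perm[k]);
      }
      double run = 0.0;
      for (int i = 0; i < n; ++i) {
        run += perm[i];
        s[i + 1] = run;
      }
      if (exceeds_scan(s.data(), n, xbar, min_width, u_obs)) {
        ++exceed;
        if (exceed >= max_exceed) {
          decided = true;
          significant = false;
          ++done;
          break;
        }
      }
    }
    if (!decided && done < n_perm) {
      // P(X <= exceed | m = done, p = alpha) < stop_conf => stop early
      if (R::pbinom(exceed, done, alpha, 1, 0) < stop_conf) {
        decided = true;
        significant = true;
      }
    }
  }
  double p = (exceed + 1.0) / (done + 1.0);
  if (!decided) significant = p < alpha;
  if (decided && !significant) p = std::max(p, alpha);
  return List::create(_["p"] = p, _["significant"] = significant,
                      _["n_perm_used"] = done, _["exceed"] = exceed);
}
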