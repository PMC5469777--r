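// Circular binary segmentation inner loops: exhaustive max-|t| arc scan and
// permutation significance. Kept in C++ because every split test scans
// O(n^2) arcs and the permutation test repeats that scan up to n_perm
// times. The permutation shuffle uses a self-contained mt19937 Fisher-Yates
// so results are bit-identical across platforms and R versions.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pooled-variance two-sample t between the arc [i, j) and its (circular)
// complement, from prefix sums. Conventions: t = 0 when the pooled variance
// is 0 and the means agree; +/-1e12 surrogate when the variance is 0 but
// the means differ. Degrees of freedom <= 0 are treated as zero variance.
static inline double arc_t(const std::vector<double>& S,
                           const std::vector<double>& Q,
                           int i, int j, int n) {
  const int n1 = j - i;
  const int n2 = n - n1;
  const double s1 = S[j] - S[i];
  const double q1 = Q[j] - Q[i];
  const double s2 = S[n] - s1;
  const double q2 = Q[n] - q1;
  const double m1 = s1 / n1;
  const double m2 = s2 / n2;
  double ss1 = q1 - s1 * s1 / n1; if (ss1 < 0) ss1 = 0;
  double ss2 = q2 - s2 * s2 / n2; if (ss2 < 0) ss2 = 0;
  const int df = n - 2;
  double sp2 = (df > 0) ? (ss1 + ss2) / df : 0.0;
  if (sp2 <= 0.0) {
    if (std::fabs(m1 - m2) <= 1e-12) return 0.0;
    return (m1 > m2) ? 1e12 : -1e12;
  }
  return (m1 - m2) / std::sqrt(sp2 * (1.0 / n1 + 1.0 / n2));
}

static void prefix_sums(const double* x, int n,
                        std::vector<double>& S, std::vector<double>& Q) {
  S.assign(n + 1, 0.0);
  Q.assign(n + 1, 0.0);
  long double s = 0.0L, q = 0.0L;
  for (int k = 0; k < n; ++k) {
    const double xx = x[k] * x[k];  // square in double, accumulate long double
    s += x[k]; q += xx;
    S[k + 1] = (double)s;
    Q[k + 1] = (double)q;
  }
}

// Scan all admissible arcs (i, j), 0 <= i < j <= n, with arc length >=
// min_seg and complement length >= min_seg. Ordering of maxima: largest
// |t|, then largest signed t, then smallest i, then smallest j.
static void scan_max(const std::vector<double>& S, const std::vector<double>& Q,
                     int n, int min_seg,
                     int& best_i, int& best_j, double& best_t) {
  best_i = 0; best_j = min_seg; best_t = 0.0;
  bool have = false;
  for (int i = 0; i + min_seg <= n; ++i) {
    const int jmax = std::min(n, n - min_seg + i); // complement >= min_seg unless arc is whole? n - (j-i) >= min_seg -> j <= n - min_seg + i
    for (int j = i + min_seg; j <= jmax; ++j) {
      const double t = arc_t(S, Q, i, j, n);
      const double at = std::fabs(t);
      const double ab = std::fabs(best_t);
      if (!have || at > ab || (at == ab && t > best_t)) {
        best_i = i; best_j = j; best_t = t;
        have = true;
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_max_t_arc")]]
NumericVector cpp_max_t_arc(NumericVector x, int min_seg) {
  const int n = x.size();
  if (n < 2 * min_seg) stop("sequence too short for min_seg_windows");
  std::vector<double> S, Q;
  prefix_sums(REAL(x), n, S, Q);
  int bi, bj; double bt;
  scan_max(S, Q, n, min_seg, bi, bj, bt);
  return NumericVector::create((double)bi, (double)bj, bt);
}

// Permutation p-value for the observed max |t|. Shuffles are seeded
// mt19937 Fisher-Yates; p uses the add-one estimator
// (1 + #{perm max|t| >= observed}) / (1 + n_done). With early_stop, the
// loop ends as soon as enough exceedances guarantee p >= alpha; the
// returned estimate then still satisfies p >= alpha.
// [[Rcpp::export(name = ".cpp_perm_pvalue")]]
double cpp_perm_pvalue(NumericVector x, double observed, int min_seg,
                       int n_perm, int seed, double alpha, bool early_stop) {
  const int n = x.size();
  std::vector<double> v(REAL(x), REAL(x) + n);
  std::vector<double> S, Q;
  std::mt19937 rng((uint32_t)seed);
  const double obs = std::fabs(observed);
  int exceed = 0;
  int done = 0;
  const double stop_at = alpha * (1.0 + n_perm) - 1.0;
  for (int p = 0; p < n_perm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      const int idx = (int)(rng() % (uint32_t)(k + 1));
      std::swap(v[k], v[idx]);
    }
    prefix_sums(v.data(), n, S, Q);
    int bi, bj; double bt;
    scan_max(S, Q, n, min_seg, bi, bj, bt);
    ++done;
    if (std::fabs(bt) >= obs) ++exceed;
    if (early_stop && exceed >= stop_at) break;
  }
  return (1.0 + exceed) / (1.0 + done);
}
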