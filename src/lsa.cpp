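#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <random>

using namespace Rcpp;

// Local similarity dynamic program over aligned index pairs (i, j) with
// |i - j| <= D.  Two tables are kept: Ppos accumulates positive runs of
// x_i * y_j, Pneg accumulates negative runs (-x_i * y_j); both reset to 0
// when the running sum drops below 0 (local alignment).  The score is the
// maximum cell over both tables; a run moves diagonally so the offset
// j - i (the delay) is constant along it.

struct LsBest {
  double score;   // raw (not length-normalised)
  int delay;      // j - i at the maximising cell
  int sign;       // +1 if the positive table attains the max
};

// Tie policy: larger score; then smaller |delay|; then positive delay;
// then positive sign.
static inline bool better(double s, int d, int sg, const LsBest &b, double eps) {
  if (s > b.score + eps) return true;
  if (s < b.score - eps) return false;
  int ad = d < 0 ? -d : d, abd = b.delay < 0 ? -b.delay : b.delay;
  if (ad != abd) return ad < abd;
  if (d != b.delay) return d > b.delay;
  return sg > b.sign;
}

static LsBest ls_dp(const double *x, const double *y, int n, int D) {
  // tables indexed [i][j], stored as (n+1) x (n+1); only |i-j| <= D visited
  std::vector<double> Ppos((n + 1) * (n + 1), 0.0), Pneg((n + 1) * (n + 1), 0.0);
  const double eps = 1e-12;
  LsBest best = {0.0, 0, +1};
  int w = n + 1;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - D), jhi = std::min(n, i + D);
    for (int j = jlo; j <= jhi; ++j) {
      double prod = x[i - 1] * y[j - 1];
      double pp = Ppos[(i - 1) * w + (j - 1)] + prod;
      double pn = Pneg[(i - 1) * w + (j - 1)] - prod;
      if (pp < 0) pp = 0;
      if (pn < 0) pn = 0;
      Ppos[i * w + j] = pp;
      Pneg[i * w + j] = pn;
      int d = j - i;
      if (better(pp, d, +1, best, eps)) best = {pp, d, +1};
      if (better(pn, d, -1, best, eps)) best = {pn, d, -1};
    }
  }
  return best;
}

// score-only variant for the permutation loop: rolling rows, only the
// band of offsets d = j - i in [-D, D] is kept (a run moves diagonally,
// so cell (i, j) depends on (i-1, j-1), i.e. the same offset d)
static inline double ls_score_raw(const double *x, const double *y, int n, int D,
                                  std::vector<double> &Ppos, std::vector<double> &Pneg) {
  // Ppos/Pneg sized 2*D+1, indexed by d + D; runs along a fixed offset
  std::fill(Ppos.begin(), Ppos.end(), 0.0);
  std::fill(Pneg.begin(), Pneg.end(), 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    int dlo = std::max(-D, 1 - i), dhi = std::min(D, n - i);
    for (int d = dlo; d <= dhi; ++d) {
      double prod = x[i - 1] * y[i + d - 1];
      double pp = Ppos[d + D] + prod;
      double pn = Pneg[d + D] - prod;
      if (pp < 0) pp = 0;
      if (pn < 0) pn = 0;
      Ppos[d + D] = pp;
      Pneg[d + D] = pn;
      if (pp > best) best = pp;
      if (pn > best) best = pn;
    }
  }
  return best;
}

// [[Rcpp::export]]
List ls_dp_cpp(NumericVector x, NumericVector y, int max_delay) {
  int n = x.size();
  if ((int)y.size() != n) stop("series lengths differ");
  if (max_delay < 0 || max_delay >= n) stop("max_delay must satisfy 0 <= D < n");
  LsBest b = ls_dp(REAL(x), REAL(y), n, max_delay);
  return List::create(_["ls_score"] = b.score / n,
                      _["sign"] = b.sign,
                      _["best_delay"] = b.delay);
}

// deterministic bounded draw (rejection sampling; avoids implementation-
// defined std::shuffle behaviour)
static inline uint32_t bounded(std::mt19937 &g, uint32_t m) {
  uint32_t lim = UINT32_MAX - UINT32_MAX % m;
  uint32_t r;
  do { r = g(); } while (r >= lim);
  return r % m;
}

// Permutation p-value for the LS score: y is permuted, x fixed.  For
// n <= exact_below all n! orderings of y are enumerated (identity included)
// and p = #{LS_perm >= LS_obs} / n!; otherwise Monte-Carlo with the
// add-one correction p = (#{>=} + 1) / (n_perm + 1).
// [[Rcpp::export]]
List ls_perm_pvalue_cpp(NumericVector x, NumericVector y, int max_delay,
                        int n_perm, int exact_below, int seed) {
  int n = x.size();
  if ((int)y.size() != n) stop("series lengths differ");
  if (max_delay < 0 || max_delay >= n) stop("max_delay must satisfy 0 <= D < n");
  const double *xp = REAL(x);
  std::vector<double> Ppos(2 * max_delay + 1), Pneg(2 * max_delay + 1);
  double obs = ls_score_raw(xp, REAL(y), n, max_delay, Ppos, Pneg);
  const double eps = 1e-9;

  bool exact = n <= exact_below;
  double p;
  long n_used;
  if (exact) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::vector<double> yp(n);
    long total = 0, count = 0;
    do {
      for (int i = 0; i < n; ++i) yp[i] = y[idx[i]];
      double s = ls_score_raw(xp, yp.data(), n, max_delay, Ppos, Pneg);
      if (s >= obs - eps) ++count;
      ++total;
    } while (std::next_permutation(idx.begin(), idx.end()));
    p = (double)count / (double)total;
    n_used = total;
  } else {
    if (n_perm < 99) stop("n_perm must be >= 99 in Monte-Carlo mode");
    std::mt19937 gen((uint32_t)seed);
    std::vector<double> yp(y.begin(), y.end());
    long count = 0;
    for (int b = 0; b < n_perm; ++b) {
      // Fisher-Yates
      for (int i = n - 1; i > 0; --i) {
        int j = (int)bounded(gen, (uint32_t)(i + 1));
        std::swap(yp[i], yp[j]);
      }
      double s = ls_score_raw(xp, yp.data(), n, max_delay, Ppos, Pneg);
      if (s >= obs - eps) ++count;
    }
    p = (double)(count + 1) / (double)(n_perm + 1);
    n_used = n_perm;
  }
  return List::create(_["p_value"] = p,
                      _["exact"] = exact,
                      _["n_perm"] = (double)n_used,
                      _["observed_raw"] = obs);
}
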