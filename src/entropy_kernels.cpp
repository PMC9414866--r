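#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise window-matching kernels for the bidimensional sample, fuzzy and
// distribution entropies. All three enumerate dense stride-1 square windows
// and compare them under the Chebyshev (max absolute difference) distance;
// the O(pairs) inner loops live here, everything else stays in R.

// Match densities Phi_m, Phi_{m+1} for 2-D sample entropy.
// Both stages share the same top-aligned anchor grid: top-left corners
// (i, j) with i in [0, H-m), j in [0, W-m), so every anchor admits both an
// m x m and an (m+1) x (m+1) window and the ratio Phi_{m+1}/Phi_m keeps its
// conditional-probability reading. Self-pairs are excluded.
// [[Rcpp::export]]
NumericVector cpp_sampen_phi(NumericMatrix x, int m, double r) {
  const int H = x.nrow(), W = x.ncol();
  const int ah = H - m, aw = W - m;
  if (ah < 1 || aw < 1) stop("patch too small for the requested window size");
  const long nw = (long)ah * aw;
  if (nw < 2) stop("need at least two windows");
  double cm = 0.0, cm1 = 0.0;
  for (long p = 0; p < nw; ++p) {
    const int pi = (int)(p % ah), pj = (int)(p / ah);
    for (long q = p + 1; q < nw; ++q) {
      const int qi = (int)(q % ah), qj = (int)(q / ah);
      // m x m stage, early exit once the tolerance is exceeded
      bool ok = true;
      for (int b = 0; b < m && ok; ++b)
        for (int a = 0; a < m; ++a) {
          if (std::fabs(x(pi + a, pj + b) - x(qi + a, qj + b)) > r) {
            ok = false;
            break;
          }
        }
      if (!ok) continue;
      cm += 2.0;  // unordered pair counted once for each ordering
      // extend by the bordering column b = m and row a = m
      for (int a = 0; a <= m && ok; ++a)
        if (std::fabs(x(pi + a, pj + m) - x(qi + a, qj + m)) > r) ok = false;
      for (int b = 0; b < m && ok; ++b)
        if (std::fabs(x(pi + m, pj + b) - x(qi + m, qj + b)) > r) ok = false;
      if (ok) cm1 += 2.0;
    }
  }
  const double denom = (double)nw * (nw - 1);
  return NumericVector::create(cm / denom, cm1 / denom);
}

// Fuzzy membership densities Phi_m(r), Phi_{m+1}(r). Windows are optionally
// mean-centered (local baseline removal) before the Chebyshev distance, and
// similarity is the exponential membership exp(-d^n / r).
// [[Rcpp::export]]
NumericVector cpp_fuzzen_phi(NumericMatrix x, int m, double r, double n,
                             bool center) {
  const int H = x.nrow(), W = x.ncol();
  const int ah = H - m, aw = W - m;
  if (ah < 1 || aw < 1) stop("patch too small for the requested window size");
  const long nw = (long)ah * aw;
  if (nw < 2) stop("need at least two windows");
  if (r <= 0) stop("fuzzy tolerance r must be positive");
  const int m1 = m + 1;
  const int km = m * m, km1 = m1 * m1;
  // flatten windows once (column-major inside the window)
  std::vector<double> Wm((size_t)nw * km), Wm1((size_t)nw * km1);
  for (long p = 0; p < nw; ++p) {
    const int pi = (int)(p % ah), pj = (int)(p / ah);
    double s1 = 0.0;
    double* wp1 = &Wm1[(size_t)p * km1];
    for (int b = 0; b < m1; ++b)
      for (int a = 0; a < m1; ++a) {
        const double v = x(pi + a, pj + b);
        wp1[b * m1 + a] = v;
        s1 += v;
      }
    double s = 0.0;
    double* wp = &Wm[(size_t)p * km];
    for (int b = 0; b < m; ++b)
      for (int a = 0; a < m; ++a) {
        const double v = x(pi + a, pj + b);
        wp[b * m + a] = v;
        s += v;
      }
    if (center) {
      const double mu = s / km, mu1 = s1 / km1;
      for (int k = 0; k < km; ++k) wp[k] -= mu;
      for (int k = 0; k < km1; ++k) wp1[k] -= mu1;
    }
  }
  // d^n without the libm pow() for the common integer exponents
  const bool n_is_2 = (n == 2.0), n_is_1 = (n == 1.0);
  double sm = 0.0, sm1 = 0.0;
  for (long p = 0; p < nw; ++p) {
    const double* wp = &Wm[(size_t)p * km];
    const double* wp1 = &Wm1[(size_t)p * km1];
    for (long q = p + 1; q < nw; ++q) {
      const double* wq = &Wm[(size_t)q * km];
      double d = 0.0;
      for (int k = 0; k < km; ++k) {
        const double dd = std::fabs(wp[k] - wq[k]);
        if (dd > d) d = dd;
      }
      sm += std::exp(-(n_is_2 ? d * d : (n_is_1 ? d : std::pow(d, n))) / r);
      const double* wq1 = &Wm1[(size_t)q * km1];
      double d1 = 0.0;
      for (int k = 0; k < km1; ++k) {
        const double dd = std::fabs(wp1[k] - wq1[k]);
        if (dd > d1) d1 = dd;
      }
      sm1 += std::exp(-(n_is_2 ? d1 * d1 : (n_is_1 ? d1 : std::pow(d1, n))) / r);
    }
  }
  const double denom = (double)nw * (nw - 1) / 2.0;
  return NumericVector::create(sm / denom, sm1 / denom);
}

// Histogram of all pairwise Chebyshev window distances for 2-D distribution
// entropy. Uses the full window set (all (H-m+1) x (W-m+1) anchors), self
// pairs excluded. Bins are M equal intervals spanning (0, d_max]; a zero
// distance falls in bin 1, and if every distance is zero all mass is in
// bin 1. Returns counts over unordered pairs (probabilities match the
// ordered-pair definition by symmetry).
// [[Rcpp::export]]
IntegerVector cpp_disten_hist(NumericMatrix x, int m, int M) {
  const int H = x.nrow(), W = x.ncol();
  const int ah = H - m + 1, aw = W - m + 1;
  if (ah < 1 || aw < 1) stop("patch too small for the requested window size");
  const long nw = (long)ah * aw;
  if (nw < 2) stop("need at least two windows");
  const int km = m * m;
  std::vector<double> Wm((size_t)nw * km);
  for (long p = 0; p < nw; ++p) {
    const int pi = (int)(p % ah), pj = (int)(p / ah);
    double* wp = &Wm[(size_t)p * km];
    for (int b = 0; b < m; ++b)
      for (int a = 0; a < m; ++a) wp[b * m + a] = x(pi + a, pj + b);
  }
  const long npair = nw * (nw - 1) / 2;
  std::vector<double> dist((size_t)npair);
  double dmax = 0.0;
  long t = 0;
  for (long p = 0; p < nw; ++p) {
    const double* wp = &Wm[(size_t)p * km];
    for (long q = p + 1; q < nw; ++q, ++t) {
      const double* wq = &Wm[(size_t)q * km];
      double d = 0.0;
      for (int k = 0; k < km; ++k) {
        const double dd = std::fabs(wp[k] - wq[k]);
        if (dd > d) d = dd;
      }
      dist[(size_t)t] = d;
      if (d > dmax) dmax = d;
    }
  }
  IntegerVector counts(M);
  if (dmax == 0.0) {
    counts[0] = (int)npair;
    return counts;
  }
  for (long i = 0; i < npair; ++i) {
    const double d = dist[(size_t)i];
    int bin = (d <= 0.0) ? 1 : (int)std::ceil(d / dmax * M);
    if (bin < 1) bin = 1;
    if (bin > M) bin = M;
    counts[bin - 1] += 1;
  }
  return counts;
}
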