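#include <Rcpp.h>
using namespace Rcpp;

// Superposition of unit-height Gaussian difference functions:
//   F(x) = sum_j exp(-(c_j - x)^2 / s)
// where s is sigma (or sigma^2 upstream). Equal widths imply every local
// maximum of F lies in [min(c), max(c)]: outside the hull all terms are
// strictly monotone toward it.
static double superpose(const std::vector<double>& c, double s, double x) {
  double f = 0.0;
  for (double cj : c) {
    double d = cj - x;
    f += std::exp(-(d * d) / s);
  }
  return f;
}

// [[Rcpp::export(name = ".peak_superposition")]]
NumericVector peak_superposition_cpp(NumericVector centers, double sigma) {
  if (sigma <= 0) stop("sigma must be positive");
  const int n = centers.size();
  if (n == 0) {
    return NumericVector::create(NA_REAL, 0.0);
  }
  std::vector<double> c(centers.begin(), centers.end());
  double lo = *std::min_element(c.begin(), c.end());
  double hi = *std::max_element(c.begin(), c.end());
  if (hi - lo < 1e-14) {
    // all centers coincide: F peaks exactly at the common center with value n
    return NumericVector::create(lo, (double)n);
  }

  // Bracketing grid over the convex hull of the centers. Step is small
  // relative to the Gaussian width sqrt(sigma/2), so every basin is sampled.
  // Every grid-local maximum is refined: near-tied local maxima can differ
  // by less than the grid sampling error, so refining only the best grid
  // cell could return the wrong basin.
  double h = 0.02 * std::sqrt(sigma);
  int m = std::max(2, (int)std::ceil((hi - lo) / h) + 1);
  std::vector<double> gx(m), gf(m);
  for (int i = 0; i < m; ++i) {
    gx[i] = lo + i * (hi - lo) / (m - 1);
    gf[i] = superpose(c, sigma, gx[i]);
  }
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double best_x = gx[0], best_f = -1.0;
  for (int i = 0; i < m; ++i) {
    bool locmax = (i == 0 || gf[i] >= gf[i - 1]) &&
                  (i == m - 1 || gf[i] >= gf[i + 1]);
    if (!locmax) continue;
    double a = std::max(lo, gx[i] - h), b = std::min(hi, gx[i] + h);
    double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
    double f1 = superpose(c, sigma, x1), f2 = superpose(c, sigma, x2);
    while (b - a > 1e-12) {
      if (f1 >= f2) { // keep the left interval on ties: smallest-x maximizer
        b = x2; x2 = x1; f2 = f1;
        x1 = b - gr * (b - a);
        f1 = superpose(c, sigma, x1);
      } else {
        a = x1; x1 = x2; f1 = f2;
        x2 = a + gr * (b - a);
        f2 = superpose(c, sigma, x2);
      }
    }
    double xs = 0.5 * (a + b);
    double fs = superpose(c, sigma, xs);
    if (fs < gf[i]) { xs = gx[i]; fs = gf[i]; }
    if (fs > best_f) { // strict: the smallest-x basin wins exact ties
      best_f = fs;
      best_x = xs;
    }
  }
  return NumericVector::create(best_x, best_f);
}
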