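#include <Rcpp.h>
using namespace Rcpp;

// Peak of the assignment-maximized superposition.
//
// Channels with a unique binding contribute fixed centers (`singles`).
// Each letter type with several candidate occurrence matchings contributes,
// at any probe x, the best of its options: for fixed x the types are
// independent, so
//   max over joint assignments of max_x F(x)
//     = max_x [ sum over singles + sum over types of the per-type maximum ].
// The right-hand side is an upper envelope of smooth functions; it is
// scanned on the same bracketing grid as the plain peak search and refined
// by golden section. Returns the peak location, its value, and the 1-based
// per-type option index attaining it (ties: first option).
//
// `type_opts` is a list of numeric matrices, one per letter type, with one
// row per candidate matching and one column per matched occurrence pair
// (entries are the d values of that matching).

struct TypeOpts {
  const double* p; // column-major nrow x ncol
  int nrow, ncol;
};

static double type_best(const TypeOpts& t, double s, double x, int* which) {
  double best = R_NegInf;
  int bi = 0;
  for (int r = 0; r < t.nrow; ++r) {
    double f = 0.0;
    for (int c = 0; c < t.ncol; ++c) {
      double d = t.p[r + c * t.nrow] - x;
      f += std::exp(-(d * d) / s);
    }
    if (f > best) { best = f; bi = r; }
  }
  if (which) *which = bi + 1;
  return best;
}

static double envelope(const std::vector<double>& singles,
                       const std::vector<TypeOpts>& types,
                       double s, double x) {
  double f = 0.0;
  for (double c : singles) {
    double d = c - x;
    f += std::exp(-(d * d) / s);
  }
  for (const TypeOpts& t : types) f += type_best(t, s, x, nullptr);
  return f;
}

// [[Rcpp::export(name = ".peak_envelope")]]
List peak_envelope_cpp(NumericVector singles, List type_opts, double sigma) {
  if (sigma <= 0) stop("sigma must be positive");
  const int ntypes = type_opts.size();
  std::vector<double> sing(singles.begin(), singles.end());
  std::vector<TypeOpts> types(ntypes);
  std::vector<NumericMatrix> keep; // hold SEXPs alive
  keep.reserve(ntypes);
  double lo = R_PosInf, hi = R_NegInf;
  int nchan = sing.size();
  for (double c : sing) { lo = std::min(lo, c); hi = std::max(hi, c); }
  for (int t = 0; t < ntypes; ++t) {
    keep.emplace_back(as<NumericMatrix>(type_opts[t]));
    NumericMatrix& m = keep.back();
    types[t] = {REAL(m), m.nrow(), m.ncol()};
    nchan += m.ncol();
    for (int j = 0; j < m.nrow() * m.ncol(); ++j) {
      lo = std::min(lo, types[t].p[j]);
      hi = std::max(hi, types[t].p[j]);
    }
  }
  IntegerVector choice(ntypes, 1);
  if (nchan == 0) {
    return List::create(_["x_star"] = NA_REAL, _["f_star"] = 0.0,
                        _["choice"] = choice);
  }
  if (hi - lo < 1e-14) { // every candidate center coincides
    return List::create(_["x_star"] = lo, _["f_star"] = (double)nchan,
                        _["choice"] = choice);
  }

  // scan, then refine every grid-local maximum (near-tied basins can differ
  // by less than the grid sampling error)
  double h = 0.02 * std::sqrt(sigma);
  int m = std::max(2, (int)std::ceil((hi - lo) / h) + 1);
  std::vector<double> gx(m), gf(m);
  for (int i = 0; i < m; ++i) {
    gx[i] = lo + i * (hi - lo) / (m - 1);
    gf[i] = envelope(sing, types, sigma, gx[i]);
  }
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double xs = gx[0], fs = -1.0;
  for (int i = 0; i < m; ++i) {
    bool locmax = (i == 0 || gf[i] >= gf[i - 1]) &&
                  (i == m - 1 || gf[i] >= gf[i + 1]);
    if (!locmax) continue;
    double a = std::max(lo, gx[i] - h), b = std::min(hi, gx[i] + h);
    double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
    double f1 = envelope(sing, types, sigma, x1);
    double f2 = envelope(sing, types, sigma, x2);
    while (b - a > 1e-12) {
      if (f1 >= f2) {
        b = x2; x2 = x1; f2 = f1;
        x1 = b - gr * (b - a);
        f1 = envelope(sing, types, sigma, x1);
      } else {
        a = x1; x1 = x2; f1 = f2;
        x2 = a + gr * (b - a);
        f2 = envelope(sing, types, sigma, x2);
      }
    }
    double cx = 0.5 * (a + b);
    double cf = envelope(sing, types, sigma, cx);
    if (cf < gf[i]) { cx = gx[i]; cf = gf[i]; }
    if (cf > fs) { fs = cf; xs = cx; }
  }

  double total = 0.0;
  for (double c : sing) {
    double d = c - xs;
    total += std::exp(-(d * d) / sigma);
  }
  for (int t = 0; t < ntypes; ++t) {
    int wi = 1;
    total += type_best(types[t], sigma, xs, &wi);
    choice[t] = wi;
  }
  return List::create(_["x_star"] = xs, _["f_star"] = total,
                      _["choice"] = choice);
}
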