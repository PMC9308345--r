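// Exact Devroye-type rejection sampler for the Polya-Gamma PG(1, c) law,
// plus a truncated sum-of-gammas sampler for general (non-integer) shape.
// All randomness comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

static const double PG_TRUNC = 0.64; // series switch point of the J*(1,0) density

// n-th coefficient of the alternating series for the J*(1, 0) density,
// using the x <= t (inverse-Gaussian-like) or x > t (exponential-like) form.
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > PG_TRUNC) {
    return M_PI * np5 * std::exp(-0.5 * np5 * np5 * M_PI * M_PI * x);
  }
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * np5 *
         std::exp(-2.0 * np5 * np5 / x);
}

// CDF of the inverse-Gaussian(mu, lambda = 1) law; mu may be +Inf (Levy case).
static double pigauss(double x, double mu) {
  double z = (std::isfinite(mu) && mu > 0.0) ? 1.0 / mu : 0.0;
  double rx = 1.0 / std::sqrt(x);
  double b = rx * (x * z - 1.0);
  double a = -rx * (x * z + 1.0);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(a, 0.0, 1.0, 1, 0);
}

// Inverse-Gaussian(mu = 1/Z, lambda = 1) truncated to (0, PG_TRUNC).
static double rtigauss(double Z) {
  double t = PG_TRUNC;
  double mu = (Z > 0.0) ? 1.0 / Z : R_PosInf;
  double X;
  if (!(mu < t)) {
    // mu >= t: rejection from the Levy proposal tilted by exp(-Z^2 X / 2)
    for (;;) {
      double E1, E2;
      do {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      } while (E1 * E1 > 2.0 * E2 / t);
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      if (R::unif_rand() <= std::exp(-0.5 * Z * Z * X)) return X;
    }
  }
  // mu < t: draw inverse-Gaussian until it lands in (0, t)
  for (;;) {
    double Y = R::norm_rand();
    Y = Y * Y;
    double muY = mu * Y;
    X = mu + 0.5 * mu * muY -
        0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
    if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    if (X < t) return X;
  }
}

// One exact draw from PG(1, c) (Devroye's alternating-series method).
double rpg1(double c) {
  double Z = 0.5 * std::fabs(c);
  double fz = 0.125 * M_PI * M_PI + 0.5 * Z * Z;
  double p = (M_PI / (2.0 * fz)) * std::exp(-fz * PG_TRUNC);
  double q = 2.0 * std::exp(-Z) * pigauss(PG_TRUNC, (Z > 0.0) ? 1.0 / Z : R_PosInf);

  for (;;) {
    double X;
    if (R::unif_rand() < p / (p + q)) {
      X = PG_TRUNC + R::exp_rand() / fz; // truncated exponential tail
    } else {
      X = rtigauss(Z);
    }
    // series accept/reject (squeeze)
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X; // accept
      } else {
        S += a_coef(n, X);
        if (Y > S) break; // reject, restart
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".rpg_devroye_cpp")]]
NumericVector rpg_devroye_cpp(int n, int b, NumericVector c) {
  if (b < 1) stop("shape parameter b must be >= 1");
  NumericVector out(n);
  int nc = c.size();
  for (int i = 0; i < n; ++i) {
    double ci = c[i % nc];
    double s = 0.0;
    for (int k = 0; k < b; ++k) s += rpg1(ci); // PG(b,c) = b-fold PG(1,c) convolution
    out[i] = s;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".rpg_gamma_sum_cpp")]]
NumericVector rpg_gamma_sum_cpp(int n, double b, NumericVector c, int nterms) {
  if (b <= 0.0) stop("shape parameter b must be > 0");
  if (nterms < 1) stop("nterms must be >= 1");
  NumericVector out(n);
  int nc = c.size();
  const double fourpi2 = 4.0 * M_PI * M_PI;
  for (int i = 0; i < n; ++i) {
    double ci = c[i % nc];
    double c2 = ci * ci / fourpi2;
    double s = 0.0;
    for (int k = 1; k <= nterms; ++k) {
      double d = (k - 0.5) * (k - 0.5) + c2;
      s += R::rgamma(b, 1.0) / d;
    }
    out[i] = s / (2.0 * M_PI * M_PI);
  }
  return out;
}
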