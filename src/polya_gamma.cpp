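// Exact Polya-Gamma PG(1, z) sampler (Devroye-type alternating-series
// rejection, as in Polson, Scott & Windle's augmentation scheme).
// Uses R's RNG so draws are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;

// Piecewise coefficients a_n(x) of the J*(1,0) density series.
static double a_coef(int n, double x) {
  double d = n + 0.5;
  if (x > TRUNC)
    return M_PI * d * std::exp(-d * d * M_PI * M_PI * x / 2.0);
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * d * std::exp(-2.0 * d * d / x);
}

// Inverse-Gaussian IG(1/z, 1) truncated to (0, t).
static double rtigauss(double z, double t) {
  double X = t + 1.0;
  double mu = 1.0 / z;
  if (mu > t) {
    // z small: rejection from truncated inverse-chi-square
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double E1, E2;
      do {
        E1 = exp_rand();
        E2 = exp_rand();
      } while (E1 * E1 > 2.0 * E2 / t);
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = std::exp(-0.5 * z * z * X);
    }
  } else {
    while (X > t) {
      double Y = norm_rand();
      Y = Y * Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * muY - 0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
      if (unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// Probability of proposing from the (truncated-)exponential right piece.
static double mass_texpon(double z) {
  double t = TRUNC;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// One draw of PG(1, zin) = J*(1, zin/2) / 4.
static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double X;
  for (;;) {
    if (unif_rand() < mass_texpon(z)) {
      X = TRUNC + exp_rand() / fz;
    } else {
      X = rtigauss(z, TRUNC);
    }
    double S = a_coef(0, X);
    double Y = unif_rand() * S;
    int n = 0;
    bool accept = false;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) { accept = true; break; }
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
    if (accept) break;
  }
  return X / 4.0;
}

// [[Rcpp::export]]
NumericVector rpg_cpp(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  PutRNGstate();
  return out;
}
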