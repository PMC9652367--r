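// Devroye-style alternating-series sampler for the Polya-Gamma
// distribution PG(1, c), the auxiliary variable that turns the logistic
// likelihood into a conditionally Gaussian one.  Uses R's RNG so that
// set.seed() on the R side makes every draw reproducible.
#include <Rcpp.h>
#include "pg.h"

using namespace Rcpp;

static const double TRUNCPT = 0.64; // split point of the two proposal pieces

// n-th coefficient of the alternating series for the J*(1) density at x,
// using the left (inverse-Gaussian-like) expansion below TRUNCPT and the
// right (exponential-like) expansion above it.
static double a_coef(int n, double x) {
  double np5 = n + 0.5;
  if (x > TRUNCPT)
    return M_PI * np5 * std::exp(-np5 * np5 * M_PI * M_PI * x / 2.0);
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * np5 *
         std::exp(-2.0 * np5 * np5 / x);
}

// probability that the mixture proposal draws from the truncated
// exponential tail rather than the truncated inverse-Gaussian head
static double mass_texpon(double z) {
  double t = TRUNCPT;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t)
static double rtigauss(double z, double t) {
  double x = t + 1.0;
  if (z * t < 1.0) {
    // mean beyond the truncation point: rejection from a scaled
    // inverse-chi-square restricted to (0, t)
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = norm_rand();
      y *= y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// one PG(1, c) draw; PG(1, c) = J*(1, |c|/2) / 4
double rpg1(double c) {
  double z = std::fabs(c) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  for (;;) {
    double x;
    if (unif_rand() < mass_texpon(z))
      x = TRUNCPT + exp_rand() / fz;
    else
      x = rtigauss(z, TRUNCPT);
    // squeeze accept/reject on the alternating partial sums
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    for (int n = 1;; ++n) {
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

// [[Rcpp::export(name = ".rpg_devroye")]]
NumericVector rpg_devroye(int n, NumericVector c) {
  NumericVector out(n);
  R_xlen_t m = c.size();
  for (int i = 0; i < n; ++i) out[i] = rpg1(c[i % m]);
  return out;
}
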