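#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Collapsed adaptive Metropolis sampler for the logit-scale trend model
//   y_i = alpha + beta * x_i + eps_i,  eps_i ~ N(0, sigma^2).
//
// The posterior of (alpha, beta, sigma) at n = 4 observations is strongly
// funnel-shaped: the coefficients' conditional scale is proportional to
// sigma, whose own posterior is heavy-tailed. A joint random walk mixes
// poorly there, so the coefficients are integrated out analytically (their
// conditional posterior is Gaussian under both supported prior families)
// and a 1-d adaptive random walk targets the *marginal* posterior of
// u = log(sigma); (alpha, beta) are then drawn exactly from their
// conditional bivariate normal at each kept iteration. The step size is
// adapted during burn-in only. Uses R's RNG, so set.seed() governs
// determinism.
//
// prior_type 0: alpha ~ N(pp0, pp1), beta ~ N(pp2, pp3) independent of
//   sigma; sigma ~ half-Normal(0, pp4).
// prior_type 1: normal-inverse-gamma. theta | s2 ~ N(m0, s2 * P0^-1),
//   s2 ~ IG(a0, b0). prior_par = (m0[2], P0[4] row-major, a0, b0).

struct Cond {        // conditional posterior of theta given sigma
  double m[2];       // mean
  double L[2][2];    // lower Cholesky factor of the precision Lambda
  double log_det_lambda;
  double quad;       // m' Lambda m
};

static void cond_theta(double s2, const double xtx[3], const double xty[2],
                       int prior_type, const NumericVector &pp, Cond &c) {
  double P[3], pm[2];  // prior precision (packed sym: 00, 01, 11), mean
  if (prior_type == 0) {
    P[0] = 1.0 / (pp[1] * pp[1]); P[1] = 0.0; P[2] = 1.0 / (pp[3] * pp[3]);
    pm[0] = pp[0]; pm[1] = pp[2];
  } else {
    P[0] = pp[2] / s2; P[1] = pp[3] / s2; P[2] = pp[5] / s2;
    pm[0] = pp[0]; pm[1] = pp[1];
  }
  double A = xtx[0] / s2 + P[0];
  double B = xtx[1] / s2 + P[1];
  double D = xtx[2] / s2 + P[2];
  double b0 = xty[0] / s2 + P[0] * pm[0] + P[1] * pm[1];
  double b1 = xty[1] / s2 + P[1] * pm[0] + P[2] * pm[1];
  double det = A * D - B * B;
  c.m[0] = (D * b0 - B * b1) / det;
  c.m[1] = (A * b1 - B * b0) / det;
  c.log_det_lambda = std::log(det);
  c.quad = c.m[0] * (A * c.m[0] + B * c.m[1]) +
           c.m[1] * (B * c.m[0] + D * c.m[1]);
  c.L[0][0] = std::sqrt(A);
  c.L[1][0] = B / c.L[0][0];
  c.L[1][1] = std::sqrt(D - c.L[1][0] * c.L[1][0]);
  c.L[0][1] = 0.0;
}

// log posterior of u = log sigma with theta integrated out (up to a
// constant), including the Jacobian of the transform
static double log_marg(double u, int n, const double xtx[3],
                       const double xty[2], double yty,
                       int prior_type, const NumericVector &pp, Cond &c) {
  double sigma = std::exp(u), s2 = sigma * sigma;
  cond_theta(s2, xtx, xty, prior_type, pp, c);
  double lp;
  if (prior_type == 0) {
    double pm_quad = (pp[0] * pp[0]) / (pp[1] * pp[1]) +
                     (pp[2] * pp[2]) / (pp[3] * pp[3]);
    lp = -0.5 * n * std::log(s2) - 0.5 * yty / s2
         - 0.5 * pm_quad + 0.5 * c.quad - 0.5 * c.log_det_lambda;
    // half-Normal prior on sigma, Jacobian d sigma / d u = sigma
    lp += -0.5 * (sigma / pp[4]) * (sigma / pp[4]) + u;
  } else {
    double m0P0m0 = pp[0] * (pp[2] * pp[0] + pp[3] * pp[1]) +
                    pp[1] * (pp[4] * pp[0] + pp[5] * pp[1]);
    // c.quad = m' Lambda m with Lambda = (X'X + P0)/s2, and m is free of
    // s2 under this prior, so m' (X'X + P0) m = c.quad * s2
    double S = yty + m0P0m0 - c.quad * s2;
    // marginal likelihood: the sigma^-4 factors of |P0/s2| and |Lambda|
    // cancel, leaving -n/2 log s2 - S/(2 s2) + const
    double a0 = pp[6], b0 = pp[7];
    lp = -0.5 * n * std::log(s2) - 0.5 * S / s2
         - (a0 + 1.0) * std::log(s2) - b0 / s2
         + std::log(2.0) + 2.0 * u;  // IG prior on s2 + Jacobian ds2/du
  }
  return lp;
}

// [[Rcpp::export]]
List rw_chain(NumericVector x, NumericVector y,
              int prior_type, NumericVector prior_par,
              int iterations, int burn_in,
              double target_accept, double init_u, double init_step) {
  int n = x.size();
  double xtx[3] = {(double)n, 0.0, 0.0}, xty[2] = {0.0, 0.0}, yty = 0.0;
  for (int i = 0; i < n; ++i) {
    xtx[1] += x[i]; xtx[2] += x[i] * x[i];
    xty[0] += y[i]; xty[1] += x[i] * y[i];
    yty += y[i] * y[i];
  }

  Cond c, c_prop;
  double u = init_u;
  double lp = log_marg(u, n, xtx, xty, yty, prior_type, prior_par, c);
  if (!R_finite(lp)) stop("non-finite posterior at initial values");
  double log_s = std::log(init_step > 0 ? init_step : 1.0);

  int n_keep = iterations - burn_in;
  NumericMatrix draws(n_keep, 3);
  colnames(draws) = CharacterVector::create("alpha", "beta", "sigma");
  int acc_post = 0, acc_all = 0;

  for (int t = 1; t <= iterations; ++t) {
    double u_prop = u + std::exp(log_s) * R::norm_rand();
    double lp_prop = log_marg(u_prop, n, xtx, xty, yty,
                              prior_type, prior_par, c_prop);
    double log_ratio = lp_prop - lp;
    double acc_prob = (log_ratio >= 0) ? 1.0 :
                      (R_finite(log_ratio) ? std::exp(log_ratio) : 0.0);
    if (R::unif_rand() < acc_prob) {
      u = u_prop; lp = lp_prop; c = c_prop;
      ++acc_all;
      if (t > burn_in) ++acc_post;
    }
    if (t <= burn_in) {
      log_s += std::pow((double)t, -0.6) * (acc_prob - target_accept);
    } else {
      // exact conditional draw of (alpha, beta) given sigma:
      // theta = m + L^-T z, Lambda = L L^T
      double z0 = R::norm_rand(), z1 = R::norm_rand();
      double w1 = z1 / c.L[1][1];
      double w0 = (z0 - c.L[1][0] * w1) / c.L[0][0];
      int k = t - burn_in - 1;
      draws(k, 0) = c.m[0] + w0;
      draws(k, 1) = c.m[1] + w1;
      draws(k, 2) = std::exp(u);
    }
  }

  return List::create(
    _["draws"] = draws,
    _["accept_rate"] = (double)acc_post / (double)n_keep,
    _["accept_rate_all"] = (double)acc_all / (double)iterations);
}
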