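#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ln erfc(u), finite for all finite u. libm erfc underflows around u ~ 26.6;
// beyond that use the asymptotic expansion
// erfc(u) ~ exp(-u^2)/(u sqrt(pi)) * (1 - 1/(2u^2) + 3/(4u^4) - 15/(8u^6)).
static inline double log_erfc(double u) {
  if (u < 25.0) return std::log(std::erfc(u));
  double u2 = u * u;
  double s = 1.0 - 0.5 / u2 + 0.75 / (u2 * u2) - 1.875 / (u2 * u2 * u2);
  return -u2 - std::log(u * std::sqrt(M_PI)) + std::log(s);
}

// d/du ln erfc(u) = -(2/sqrt(pi)) exp(-u^2) / erfc(u)
static inline double dlog_erfc(double u) {
  return -M_2_SQRTPI * std::exp(-u * u - log_erfc(u));
}

// ln f(x; mu, sigma, tau) of the ex-Gaussian density
// f = 1/(2 tau) exp((mu - x)/tau + sigma^2/(2 tau^2)) erfc(u),
// u = ((mu - x)/sigma + sigma/tau) / sqrt(2)
static inline double exg_logpdf1(double x, double mu, double sigma, double tau) {
  double u = ((mu - x) / sigma + sigma / tau) * M_SQRT1_2;
  return -std::log(2.0 * tau) + (mu - x) / tau +
         sigma * sigma / (2.0 * tau * tau) + log_erfc(u);
}

// gradient of ln f with respect to (mu, sigma, tau)
static inline void exg_logpdf_grad1(double x, double mu, double sigma,
                                    double tau, double *g) {
  double u = ((mu - x) / sigma + sigma / tau) * M_SQRT1_2;
  double Lp = dlog_erfc(u);
  double dmu = 1.0 / tau + Lp * M_SQRT1_2 / sigma;
  double dsg = sigma / (tau * tau) +
               Lp * M_SQRT1_2 * (1.0 / tau - (mu - x) / (sigma * sigma));
  double dta = -1.0 / tau - (mu - x) / (tau * tau) -
               sigma * sigma / (tau * tau * tau) -
               Lp * M_SQRT1_2 * sigma / (tau * tau);
  g[0] = dmu; g[1] = dsg; g[2] = dta;
}

// [[Rcpp::export]]
NumericVector cpp_exg_logpdf(NumericVector x, double mu, double sigma,
                             double tau) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = exg_logpdf1(x[i], mu, sigma, tau);
  return out;
}

// stable CDF: F = Phi((x-mu)/sigma) - exp(v - ln 2 + ln erfc(u)),
// v = sigma^2/(2 tau^2) + (mu - x)/tau
static inline double exg_cdf1(double x, double mu, double sigma, double tau) {
  double u = ((mu - x) / sigma + sigma / tau) * M_SQRT1_2;
  double v = sigma * sigma / (2.0 * tau * tau) + (mu - x) / tau;
  double F = R::pnorm((x - mu) / sigma, 0.0, 1.0, 1, 0) -
             std::exp(v - M_LN2 + log_erfc(u));
  if (F < 0.0) F = 0.0;
  if (F > 1.0) F = 1.0;
  return F;
}

// [[Rcpp::export]]
NumericVector cpp_exg_cdf(NumericVector x, double mu, double sigma,
                          double tau) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = exg_cdf1(x[i], mu, sigma, tau);
  return out;
}

// log-likelihood ln L = sum ln f(x_i) and its gradient
// [[Rcpp::export]]
List cpp_lkhd(NumericVector x, double mu, double sigma, double tau) {
  double val = 0.0, g[3], gs[3] = {0.0, 0.0, 0.0};
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    val += exg_logpdf1(x[i], mu, sigma, tau);
    exg_logpdf_grad1(x[i], mu, sigma, tau, g);
    gs[0] += g[0]; gs[1] += g[1]; gs[2] += g[2];
  }
  return List::create(_["value"] = val,
                      _["grad"] = NumericVector::create(gs[0], gs[1], gs[2]));
}

// histogram least-squares objective: sum over bins of
// (density_i - f(center_i))^2, with analytic gradient (df/dtheta = f dlnf)
// [[Rcpp::export]]
List cpp_sqr(NumericVector centers, NumericVector dens, double mu,
             double sigma, double tau) {
  double val = 0.0, g[3], gs[3] = {0.0, 0.0, 0.0};
  R_xlen_t n = centers.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double f = std::exp(exg_logpdf1(centers[i], mu, sigma, tau));
    double r = dens[i] - f;
    val += r * r;
    exg_logpdf_grad1(centers[i], mu, sigma, tau, g);
    gs[0] += -2.0 * r * f * g[0];
    gs[1] += -2.0 * r * f * g[1];
    gs[2] += -2.0 * r * f * g[2];
  }
  return List::create(_["value"] = val,
                      _["grad"] = NumericVector::create(gs[0], gs[1], gs[2]));
}

static void objective(int type, NumericVector &a, NumericVector &b, double mu,
                      double sigma, double tau, double *val, double *grad) {
  if (type == 1) { // log-likelihood (maximize)
    double g[3];
    *val = 0.0; grad[0] = grad[1] = grad[2] = 0.0;
    for (R_xlen_t i = 0; i < a.size(); ++i) {
      *val += exg_logpdf1(a[i], mu, sigma, tau);
      exg_logpdf_grad1(a[i], mu, sigma, tau, g);
      grad[0] += g[0]; grad[1] += g[1]; grad[2] += g[2];
    }
  } else { // histogram sum of squares (minimize)
    double g[3];
    *val = 0.0; grad[0] = grad[1] = grad[2] = 0.0;
    for (R_xlen_t i = 0; i < a.size(); ++i) {
      double f = std::exp(exg_logpdf1(a[i], mu, sigma, tau));
      double r = b[i] - f;
      *val += r * r;
      exg_logpdf_grad1(a[i], mu, sigma, tau, g);
      grad[0] += -2.0 * r * f * g[0];
      grad[1] += -2.0 * r * f * g[1];
      grad[2] += -2.0 * r * f * g[2];
    }
  }
}

// Steepest descent/ascent with a scalar adaptive step:
//   trial = p + sense * eta * grad
// accepted steps double eta, rejected ones halve it (the same step is
// retried); steps that would drive sigma or tau non-positive are treated as
// rejections. Stops when ||grad|| <= tol * max(1, |value|), when eta
// underflows, or at max_iter. Mirrors steepest_extremum() on the R side.
// [[Rcpp::export]]
List cpp_steepest(int type, NumericVector a, NumericVector b,
                  NumericVector init, int sense, double step0, double tol,
                  int max_iter) {
  double p[3] = {init[0], init[1], init[2]};
  double val, grad[3];
  objective(type, a, b, p[0], p[1], p[2], &val, grad);
  if (!R_FINITE(val))
    stop("objective is not finite at the initial parameters");
  double eta = step0;
  int it = 0;
  bool converged = false;
  double gnorm = std::sqrt(grad[0] * grad[0] + grad[1] * grad[1] +
                           grad[2] * grad[2]);
  while (it < max_iter) {
    double tol_eff = tol * std::max(1.0, std::fabs(val));
    if (gnorm <= tol_eff) { converged = true; break; }
    ++it;
    // try a step, halving eta until it improves or underflows
    bool accepted = false;
    for (int h = 0; h < 200; ++h) {
      double q[3] = {p[0] + sense * eta * grad[0],
                     p[1] + sense * eta * grad[1],
                     p[2] + sense * eta * grad[2]};
      if (q[1] > 0.0 && q[2] > 0.0) {
        double v2, g2[3];
        objective(type, a, b, q[0], q[1], q[2], &v2, g2);
        bool better = R_FINITE(v2) &&
                      (sense > 0 ? (v2 > val) : (v2 < val));
        if (better) {
          p[0] = q[0]; p[1] = q[1]; p[2] = q[2];
          val = v2;
          grad[0] = g2[0]; grad[1] = g2[1]; grad[2] = g2[2];
          gnorm = std::sqrt(grad[0] * grad[0] + grad[1] * grad[1] +
                            grad[2] * grad[2]);
          eta *= 2.0;
          accepted = true;
          break;
        }
      }
      eta *= 0.5;
      if (eta <= 0.0 || !R_FINITE(eta)) break;
    }
    if (!accepted) { // stalled: eta exhausted without improvement
      double tol_eff2 = tol * std::max(1.0, std::fabs(val));
      converged = gnorm <= tol_eff2;
      break;
    }
  }
  if (gnorm <= tol * std::max(1.0, std::fabs(val))) converged = true;
  return List::create(_["par"] = NumericVector::create(p[0], p[1], p[2]),
                      _["value"] = val, _["n_iter"] = it,
                      _["grad_norm"] = gnorm, _["converged"] = converged);
}
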