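#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Adaptive Gauss-Hermite quadrature for the marginal likelihood of a
// logistic regression with normal random intercepts. Rows must be sorted so
// that each group's rows are contiguous; `starts` holds 0-based row offsets
// (length G + 1). `nodes`/`logw` are the Gauss-Hermite rule for
// int exp(-z^2) f(z) dz; integration is recentered at each group's
// conditional mode with Laplace curvature scaling.

static const double LOG_2PI = 1.8378770664093454836;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// conditional Bernoulli log-likelihood of rows [s, e) at offset b
static double cond_ll(const double* eta, const int* y, int s, int e, double b) {
  double ll = 0.0;
  for (int j = s; j < e; ++j) {
    double x = eta[j] + b;
    ll += y[j] * x - softplus(x);
  }
  return ll;
}

// log of int exp(cond_ll(b)) * dnorm(b; 0, sigma) db for one group,
// by adaptive GHQ; offset shifts every row's linear predictor.
static double group_aghq(const double* eta, const int* y, int s, int e,
                         double offset, double sigma,
                         const NumericVector& nodes,
                         const NumericVector& logw) {
  if (sigma < 1e-8) return cond_ll(eta, y, s, e, offset);
  double s2 = sigma * sigma;
  // Newton for the mode of f(b) = cond_ll + log prior kernel
  double b = 0.0;
  double f = cond_ll(eta, y, s, e, offset) /* b=0 */;
  for (int it = 0; it < 100; ++it) {
    double g = -b / s2, h = -1.0 / s2;
    for (int j = s; j < e; ++j) {
      double x = eta[j] + offset + b;
      double p = 1.0 / (1.0 + std::exp(-x));
      g += y[j] - p;
      h -= p * (1.0 - p);
    }
    double step = -g / h;
    if (!std::isfinite(step)) break;
    // damped update: backtrack until f improves
    double bnew = b + step;
    double fnew = cond_ll(eta, y, s, e, offset + bnew) -
                  bnew * bnew / (2.0 * s2);
    int bt = 0;
    while (fnew < f - 1e-12 && bt < 30) {
      step *= 0.5;
      bnew = b + step;
      fnew = cond_ll(eta, y, s, e, offset + bnew) - bnew * bnew / (2.0 * s2);
      ++bt;
    }
    double delta = std::fabs(bnew - b);
    b = bnew;
    f = fnew;
    if (delta < 1e-12) break;
  }
  // curvature at the mode
  double h = -1.0 / s2;
  for (int j = s; j < e; ++j) {
    double x = eta[j] + offset + b;
    double p = 1.0 / (1.0 + std::exp(-x));
    h -= p * (1.0 - p);
  }
  double tau = 1.0 / std::sqrt(-h);
  // log sum_q w_q exp(z_q^2) exp(f(b + sqrt(2) tau z_q))
  int Q = nodes.size();
  double m = -INFINITY;
  std::vector<double> vals(Q);
  for (int q = 0; q < Q; ++q) {
    double bq = b + M_SQRT2 * tau * nodes[q];
    double fq = cond_ll(eta, y, s, e, offset + bq) - bq * bq / (2.0 * s2);
    vals[q] = logw[q] + nodes[q] * nodes[q] + fq;
    if (vals[q] > m) m = vals[q];
  }
  double acc = 0.0;
  for (int q = 0; q < Q; ++q) acc += std::exp(vals[q] - m);
  // integral plus the prior's normalizing constant
  return std::log(M_SQRT2 * tau) + m + std::log(acc) -
         std::log(sigma) - 0.5 * LOG_2PI;
}

// [[Rcpp::export]]
double aghq_loglik_cpp(NumericVector eta, IntegerVector y,
                       IntegerVector starts, double sigma,
                       NumericVector nodes, NumericVector logw) {
  int G = starts.size() - 1;
  const double* pe = eta.begin();
  const int* py = y.begin();
  double ll = 0.0;
  for (int g = 0; g < G; ++g) {
    ll += group_aghq(pe, py, starts[g], starts[g + 1], 0.0, sigma,
                     nodes, logw);
  }
  return ll;
}

// Log-likelihood plus its gradient, exploiting that the derivative of the
// marginal integral is itself an integral over the conditional posterior of
// b: evaluated with the same adaptive rule. Returns the per-row posterior
// mean residual R_j = E_post[y_j - p_j(b)] (so grad_beta = X'R) and the
// derivative with respect to log sigma, E_post[b^2/sigma^2 - 1].
// [[Rcpp::export]]
List aghq_loglik_grad_cpp(NumericVector eta, IntegerVector y,
                          IntegerVector starts, double sigma,
                          NumericVector nodes, NumericVector logw) {
  int G = starts.size() - 1;
  int n = eta.size();
  int Q = nodes.size();
  const double* pe = eta.begin();
  const int* py = y.begin();
  NumericVector R(n);
  double ll = 0.0, dls = 0.0;
  double s2 = sigma * sigma;
  std::vector<double> vals(Q), bqs(Q);
  for (int g = 0; g < G; ++g) {
    int s = starts[g], e = starts[g + 1];
    // mode (same Newton as group_aghq)
    double b = 0.0;
    double f = cond_ll(pe, py, s, e, 0.0);
    for (int it = 0; it < 100; ++it) {
      double gr = -b / s2, h = -1.0 / s2;
      for (int j = s; j < e; ++j) {
        double x = pe[j] + b;
        double p = 1.0 / (1.0 + std::exp(-x));
        gr += py[j] - p;
        h -= p * (1.0 - p);
      }
      double step = -gr / h;
      if (!std::isfinite(step)) break;
      double bnew = b + step;
      double fnew = cond_ll(pe, py, s, e, bnew) - bnew * bnew / (2.0 * s2);
      int bt = 0;
      while (fnew < f - 1e-12 && bt < 30) {
        step *= 0.5;
        bnew = b + step;
        fnew = cond_ll(pe, py, s, e, bnew) - bnew * bnew / (2.0 * s2);
        ++bt;
      }
      double delta = std::fabs(bnew - b);
      b = bnew;
      f = fnew;
      if (delta < 1e-12) break;
    }
    double h = -1.0 / s2;
    for (int j = s; j < e; ++j) {
      double x = pe[j] + b;
      double p = 1.0 / (1.0 + std::exp(-x));
      h -= p * (1.0 - p);
    }
    double tau = 1.0 / std::sqrt(-h);
    double m = -INFINITY;
    for (int q = 0; q < Q; ++q) {
      double bq = b + M_SQRT2 * tau * nodes[q];
      bqs[q] = bq;
      double fq = cond_ll(pe, py, s, e, bq) - bq * bq / (2.0 * s2);
      vals[q] = logw[q] + nodes[q] * nodes[q] + fq;
      if (vals[q] > m) m = vals[q];
    }
    double acc = 0.0;
    for (int q = 0; q < Q; ++q) acc += std::exp(vals[q] - m);
    ll += std::log(M_SQRT2 * tau) + m + std::log(acc) -
          std::log(sigma) - 0.5 * LOG_2PI;
    // posterior weights and gradient accumulation
    for (int q = 0; q < Q; ++q) {
      double w = std::exp(vals[q] - m) / acc;
      double bq = bqs[q];
      dls += w * (bq * bq / s2 - 1.0);
      for (int j = s; j < e; ++j) {
        double x = pe[j] + bq;
        double p = 1.0 / (1.0 + std::exp(-x));
        R[j] += w * (py[j] - p);
      }
    }
  }
  return List::create(Named("loglik") = ll, Named("R") = R,
                      Named("dlogsigma") = dls);
}

// Nested integral for one individual: over the shared intercept b, with
// each multiplex block integrated conditionally on b.
// F(b) = sum_m log G_m(b) - b^2/(2 sI^2); outer mode found by Newton with
// numeric derivatives, then AGHQ as above.
static double ind_nested(const double* eta, const int* y,
                         const int* bstart, int bs, int be,
                         double sigma_ind, double sigma_mp,
                         const NumericVector& nodes,
                         const NumericVector& logw) {
  double s2 = sigma_ind * sigma_ind;
  auto F = [&](double b) {
    double v = -b * b / (2.0 * s2);
    for (int m = bs; m < be; ++m) {
      v += group_aghq(eta, y, bstart[m], bstart[m + 1], b, sigma_mp,
                      nodes, logw);
    }
    return v;
  };
  double b = 0.0, f = F(0.0);
  double hstep = std::max(1e-4, 1e-3 * sigma_ind);
  double fpp = -1.0 / s2;
  for (int it = 0; it < 60; ++it) {
    double fp1 = F(b + hstep), fm1 = F(b - hstep);
    double grad = (fp1 - fm1) / (2.0 * hstep);
    fpp = (fp1 - 2.0 * f + fm1) / (hstep * hstep);
    if (fpp > -1e-10) fpp = -1.0 / s2;  // safeguard: curvature lost
    double step = -grad / fpp;
    if (!std::isfinite(step)) break;
    if (step > 5.0 * sigma_ind) step = 5.0 * sigma_ind;
    if (step < -5.0 * sigma_ind) step = -5.0 * sigma_ind;
    double bnew = b + step, fnew = F(bnew);
    int bt = 0;
    while (fnew < f - 1e-12 && bt < 30) {
      step *= 0.5;
      bnew = b + step;
      fnew = F(bnew);
      ++bt;
    }
    double delta = std::fabs(bnew - b);
    b = bnew;
    f = fnew;
    if (delta < 1e-10) break;
  }
  double tau = 1.0 / std::sqrt(-fpp);
  int Q = nodes.size();
  double m = -INFINITY;
  std::vector<double> vals(Q);
  for (int q = 0; q < Q; ++q) {
    double bq = b + M_SQRT2 * tau * nodes[q];
    vals[q] = logw[q] + nodes[q] * nodes[q] + F(bq);
    if (vals[q] > m) m = vals[q];
  }
  double acc = 0.0;
  for (int q = 0; q < Q; ++q) acc += std::exp(vals[q] - m);
  return std::log(M_SQRT2 * tau) + m + std::log(acc) -
         std::log(sigma_ind) - 0.5 * LOG_2PI;
}

// [[Rcpp::export]]
double aghq_nested_loglik_cpp(NumericVector eta, IntegerVector y,
                              IntegerVector ind_block_starts,
                              IntegerVector block_starts,
                              double sigma_ind, double sigma_mp,
                              NumericVector nodes, NumericVector logw) {
  int n = ind_block_starts.size() - 1;
  const double* pe = eta.begin();
  const int* py = y.begin();
  const int* pb = block_starts.begin();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int bs = ind_block_starts[i], be = ind_block_starts[i + 1];
    if (sigma_ind < 1e-8) {
      for (int m = bs; m < be; ++m) {
        ll += group_aghq(pe, py, pb[m], pb[m + 1], 0.0, sigma_mp,
                         nodes, logw);
      }
    } else {
      ll += ind_nested(pe, py, pb, bs, be, sigma_ind, sigma_mp,
                       nodes, logw);
    }
  }
  return ll;
}
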