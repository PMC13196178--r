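#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return 0.0;
  return std::log1p(std::exp(x));
}

static inline double inv_logit(double x) {
  if (x > 35.0) return 1.0;
  if (x < -35.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Newton-Raphson logistic regression for a small (k <= 3) design matrix,
// optionally with an offset. Used for the calibration slope/intercept
// regressions evaluated once per simulation replicate on the full target
// population, where glm() overhead would dominate the engine's run time.
// [[Rcpp::export]]
NumericVector logistic_newton(const NumericMatrix& X, const IntegerVector& y,
                              const NumericVector& offset,
                              int maxit = 50, double tol = 1e-9) {
  const int n = X.nrow(), k = X.ncol();
  std::vector<double> beta(k, 0.0), grad(k), step(k);
  std::vector<double> hess(k * k);
  bool has_off = offset.size() == n;

  for (int it = 0; it < maxit; ++it) {
    std::fill(grad.begin(), grad.end(), 0.0);
    std::fill(hess.begin(), hess.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double lp = has_off ? offset[i] : 0.0;
      for (int j = 0; j < k; ++j) lp += X(i, j) * beta[j];
      double p = inv_logit(lp);
      double r = y[i] - p;
      double w = p * (1.0 - p);
      if (w < 1e-12) w = 1e-12;
      for (int j = 0; j < k; ++j) {
        grad[j] += X(i, j) * r;
        for (int l = j; l < k; ++l) hess[j * k + l] += w * X(i, j) * X(i, l);
      }
    }
    for (int j = 0; j < k; ++j)
      for (int l = 0; l < j; ++l) hess[j * k + l] = hess[l * k + j];

    // solve hess * step = grad (tiny k: Gaussian elimination with pivoting)
    std::vector<double> A(hess);
    std::vector<double> b(grad);
    std::vector<int> piv(k);
    for (int j = 0; j < k; ++j) piv[j] = j;
    for (int c = 0; c < k; ++c) {
      int pr = c;
      for (int r2 = c + 1; r2 < k; ++r2)
        if (std::fabs(A[r2 * k + c]) > std::fabs(A[pr * k + c])) pr = r2;
      if (std::fabs(A[pr * k + c]) < 1e-300)
        stop("singular information matrix in logistic_newton");
      if (pr != c) {
        for (int cc = 0; cc < k; ++cc) std::swap(A[c * k + cc], A[pr * k + cc]);
        std::swap(b[c], b[pr]);
      }
      for (int r2 = c + 1; r2 < k; ++r2) {
        double f = A[r2 * k + c] / A[c * k + c];
        for (int cc = c; cc < k; ++cc) A[r2 * k + cc] -= f * A[c * k + cc];
        b[r2] -= f * b[c];
      }
    }
    for (int c = k - 1; c >= 0; --c) {
      double s = b[c];
      for (int cc = c + 1; cc < k; ++cc) s -= A[c * k + cc] * step[cc];
      step[c] = s / A[c * k + c];
    }

    double maxstep = 0.0;
    for (int j = 0; j < k; ++j) {
      // damp huge Newton steps (near-separation)
      if (step[j] > 10.0) step[j] = 10.0;
      if (step[j] < -10.0) step[j] = -10.0;
      beta[j] += step[j];
      maxstep = std::max(maxstep, std::fabs(step[j]));
    }
    if (maxstep < tol) break;
  }
  NumericVector out(k);
  for (int j = 0; j < k; ++j) out[j] = beta[j];
  return out;
}

// Adaptive random-walk Metropolis-Hastings sampler for logistic-regression
// coefficients under ridge or lasso shrinkage priors with a hyperprior on
// the penalty. Two likelihood modes:
//   mode 0: exact Bernoulli likelihood for outcomes y given design X
//           (X includes the intercept column)
//   mode 1: multivariate-normal pseudo-likelihood for the reference
//           coefficient vector beta_hat with covariance (n I)^{-1}, where
//           I is the Fisher unit-information matrix
// Parameter vector theta = (alpha, beta_1..beta_P [, log lambda^2]).
// Priors: alpha ~ N(0, intercept_var);
//   ridge: beta_j ~ N(0, lambda^2),  lambda^2 ~ inverse-gamma(hyp_a, hyp_b)
//   lasso: beta_j ~ Laplace(0, 1/lambda), lambda^2 ~ gamma(hyp_a, rate hyp_b)
// The penalty is sampled on the log scale (Jacobian included); when
// fixed_lambda is true, lambda is held at lambda_value and the parameter
// vector excludes it.
// [[Rcpp::export]]
List mh_shrinkage(const NumericMatrix& X, const IntegerVector& y,
                  const NumericVector& beta_hat, const NumericMatrix& I_unit,
                  double n_eff, int mode, int prior_family,
                  double intercept_var, double hyp_a, double hyp_b,
                  bool fixed_lambda, double lambda_value,
                  int burn_in, int thin, int n_keep,
                  const NumericVector& init, const NumericVector& prop_scale,
                  double target_acc = 0.25) {
  const int k = (mode == 0) ? X.ncol() : beta_hat.size();
  const int d = fixed_lambda ? k : k + 1;
  const int n = (mode == 0) ? X.nrow() : 0;
  if (init.size() != d || prop_scale.size() != d)
    stop("init/prop_scale length must match parameter dimension");

  std::vector<double> theta(init.begin(), init.end());
  std::vector<double> prop(d);

  auto log_target = [&](const std::vector<double>& th) -> double {
    double ll = 0.0;
    if (mode == 0) {
      for (int i = 0; i < n; ++i) {
        double lp = 0.0;
        for (int j = 0; j < k; ++j) lp += X(i, j) * th[j];
        ll += y[i] * lp - softplus(lp);
      }
    } else {
      // -0.5 * n * (th - beta_hat)' I (th - beta_hat)
      double q = 0.0;
      for (int j = 0; j < k; ++j) {
        double s = 0.0;
        for (int l = 0; l < k; ++l) s += I_unit(j, l) * (th[l] - beta_hat[l]);
        q += (th[j] - beta_hat[j]) * s;
      }
      ll = -0.5 * n_eff * q;
    }
    // intercept prior
    double lpri = -0.5 * th[0] * th[0] / intercept_var;
    double u, lam2;
    if (fixed_lambda) {
      lam2 = lambda_value * lambda_value;
      u = std::log(lam2);
    } else {
      u = th[k];
      if (u > 700.0 || u < -700.0) return -INFINITY;
      lam2 = std::exp(u);
    }
    int P = k - 1;
    if (prior_family == 0) {  // ridge: beta_j ~ N(0, lam2)
      double ssq = 0.0;
      for (int j = 1; j < k; ++j) ssq += th[j] * th[j];
      lpri += -0.5 * P * u - 0.5 * ssq / lam2;
      if (!fixed_lambda)  // inverse-gamma(hyp_a, hyp_b) + log-scale Jacobian
        lpri += -(hyp_a + 1.0) * u - hyp_b / lam2 + u;
    } else {  // lasso: beta_j ~ Laplace(0, scale = sqrt(1/lam2))
      double sabs = 0.0;
      for (int j = 1; j < k; ++j) sabs += std::fabs(th[j]);
      double log_scale = -0.5 * u;
      lpri += -P * (std::log(2.0) + log_scale) - sabs * std::exp(-log_scale);
      if (!fixed_lambda)  // gamma(shape hyp_a, rate hyp_b) + Jacobian
        lpri += (hyp_a - 1.0) * u - hyp_b * lam2 + u;
    }
    return ll + lpri;
  };

  double lt = log_target(theta);
  if (!std::isfinite(lt)) stop("non-finite log target at initial state");

  double ls = 0.0;  // global log proposal scale, adapted during burn-in
  int total = burn_in + thin * n_keep;
  NumericMatrix draws(n_keep, k);
  int kept = 0, batch_acc = 0, batch_n = 0, batch_idx = 0;
  long acc_after = 0, n_after = 0;

  for (int it = 0; it < total; ++it) {
    double s = std::exp(ls);
    for (int j = 0; j < d; ++j)
      prop[j] = theta[j] + s * prop_scale[j] * R::norm_rand();
    double lt_prop = log_target(prop);
    bool accept = std::isfinite(lt_prop) &&
                  (std::log(R::unif_rand()) < lt_prop - lt);
    if (accept) {
      theta = prop;
      lt = lt_prop;
    }
    if (it < burn_in) {
      batch_acc += accept;
      if (++batch_n == 50) {
        ++batch_idx;
        double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_idx));
        ls += (batch_acc / 50.0 > target_acc) ? delta : -delta;
        batch_acc = 0;
        batch_n = 0;
      }
    } else {
      acc_after += accept;
      ++n_after;
      if ((it - burn_in + 1) % thin == 0 && kept < n_keep) {
        for (int j = 0; j < k; ++j) draws(kept, j) = theta[j];
        ++kept;
      }
    }
  }
  return List::create(_["draws"] = draws,
                      _["accept_rate"] = n_after ? (double)acc_after / n_after
                                                 : NA_REAL,
                      _["proposal_scale"] = std::exp(ls));
}
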