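#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// IRLS for a logistic GLM. Linear predictor clamped at +/-30 to keep the
// working weights finite under near-separation; callers treat non-convergence
// as a fit failure, not an exception.
static bool logit_irls(const arma::mat& X, const arma::vec& y, arma::vec& beta,
                       arma::mat& xtwx, int maxit, double tol,
                       bool warm = false) {
  const arma::uword p = X.n_cols;
  if (!warm) beta.zeros(p);
  arma::vec eta, mu, w, z, beta_new;
  for (int it = 0; it < maxit; ++it) {
    eta = arma::clamp(X * beta, -30.0, 30.0);
    mu = 1.0 / (1.0 + arma::exp(-eta));
    w = mu % (1.0 - mu);
    w.for_each([](arma::vec::elem_type& v) { if (v < 1e-10) v = 1e-10; });
    z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    xtwx = X.t() * Xw;
    bool ok = arma::solve(beta_new, xtwx, X.t() * (w % z),
                          arma::solve_opts::no_approx);
    if (!ok || !beta_new.is_finite()) return false;
    double step = arma::norm(beta_new - beta, "inf");
    beta = beta_new;
    if (step < tol) return true;
  }
  return false;
}

// [[Rcpp::export]]
List cpp_logit(const arma::mat& X, const arma::vec& y, int maxit = 60,
               double tol = 1e-9) {
  arma::vec beta;
  arma::mat xtwx;
  bool conv = logit_irls(X, y, beta, xtwx, maxit, tol);
  arma::mat vcov;
  arma::vec se(X.n_cols);
  se.fill(NA_REAL);
  if (conv && arma::inv_sympd(vcov, xtwx)) {
    se = arma::sqrt(vcov.diag());
  } else {
    conv = false;
    vcov.zeros(X.n_cols, X.n_cols);
  }
  return List::create(_["coef"] = beta, _["se"] = se, _["vcov"] = vcov,
                      _["converged"] = conv);
}

// Per-variant logistic regression y ~ 1 + g, one column of G at a time,
// warm-started at the null intercept. Returns k x 2 (beta, se) for the
// genotype coefficient.
// [[Rcpp::export]]
arma::mat cpp_snp_logit(const arma::mat& G, const arma::vec& y, int maxit = 40,
                        double tol = 1e-8) {
  const arma::uword n = G.n_rows, k = G.n_cols;
  arma::mat out(k, 2);
  out.fill(NA_REAL);
  arma::mat X(n, 2, arma::fill::ones);
  double pbar = arma::mean(y);
  double null_int = std::log(pbar / (1.0 - pbar));
  for (arma::uword j = 0; j < k; ++j) {
    X.col(1) = G.col(j);
    arma::vec beta = {null_int, 0.0};
    arma::mat xtwx, vcov;
    if (logit_irls(X, y, beta, xtwx, maxit, tol, true) &&
        arma::inv_sympd(vcov, xtwx)) {
      out(j, 0) = beta(1);
      out(j, 1) = std::sqrt(vcov(1, 1));
    }
  }
  return out;
}

// One warm-started IRLS pass for the 3-parameter model
// logit(p) = b0 + b1*f + b2*a, with explicit accumulators (no matrix
// allocation in the replicate loop). Returns true on convergence.
static bool irls3(const double* f, const double* a, const double* y,
                  arma::uword n, arma::vec3& b, int maxit, double tol) {
  for (int it = 0; it < maxit; ++it) {
    double S00 = 0, S01 = 0, S02 = 0, S11 = 0, S12 = 0, S22 = 0;
    double t0 = 0, t1 = 0, t2 = 0;
    for (arma::uword i = 0; i < n; ++i) {
      double eta = b(0) + b(1) * f[i] + b(2) * a[i];
      if (eta > 30) eta = 30; else if (eta < -30) eta = -30;
      double mu = 1.0 / (1.0 + std::exp(-eta));
      double w = mu * (1.0 - mu);
      if (w < 1e-10) w = 1e-10;
      double wz = w * eta + (y[i] - mu);
      S00 += w; S01 += w * f[i]; S02 += w * a[i];
      S11 += w * f[i] * f[i]; S12 += w * f[i] * a[i]; S22 += w * a[i] * a[i];
      t0 += wz; t1 += wz * f[i]; t2 += wz * a[i];
    }
    arma::mat33 A = {{S00, S01, S02}, {S01, S11, S12}, {S02, S12, S22}};
    arma::vec3 rhs = {t0, t1, t2};
    arma::vec3 bn;
    if (!arma::solve(bn, A, rhs)) return false;
    if (!bn.is_finite()) return false;
    double step = arma::abs(bn - b).max();
    b = bn;
    if (step < tol) return true;
  }
  return false;
}

// Percentile bootstrap of the two-stage estimator. Each replicate resamples
// participants with replacement (indices from R's RNG, so set.seed() governs
// determinism), refits stage 1 (exposure ~ GRS, closed form) and stage 2
// (logistic outcome ~ fitted + age, warm-started at the full-sample fit) and
// records the stage-2 coefficient on the fitted values. Failed replicates
// come back NaN.
// [[Rcpp::export]]
arma::vec cpp_boot_two_stage(const arma::vec& expo, const arma::vec& grs,
                             const arma::vec& y, const arma::vec& age,
                             int reps) {
  const arma::uword n = expo.n_elem;
  arma::vec out(reps);
  out.fill(arma::datum::nan);

  // full-sample two-stage fit for the warm start
  double gm0 = arma::mean(grs), em0 = arma::mean(expo);
  double sxx0 = arma::dot(grs - gm0, grs - gm0);
  if (sxx0 <= 0) return out;
  double slope0 = arma::dot(grs - gm0, expo - em0) / sxx0;
  arma::vec fit0 = em0 + slope0 * (grs - gm0);
  arma::vec3 bfull = {std::log(std::max(arma::mean(y), 1e-8)), 0.0, 0.0};
  if (!irls3(fit0.memptr(), age.memptr(), y.memptr(), n, bfull, 50, 1e-8))
    return out;

  arma::vec eb(n), gb(n), yb(n), ab(n), fb(n);
  for (int r = 0; r < reps; ++r) {
    for (arma::uword i = 0; i < n; ++i) {
      arma::uword idx = (arma::uword)(unif_rand() * n);
      if (idx >= n) idx = n - 1;
      eb(i) = expo(idx);
      gb(i) = grs(idx);
      yb(i) = y(idx);
      ab(i) = age(idx);
    }
    double gm = arma::mean(gb), em = arma::mean(eb);
    double sxx = arma::dot(gb - gm, gb - gm);
    if (sxx <= 0) continue;
    double slope = arma::dot(gb - gm, eb - em) / sxx;
    if (std::abs(slope) < 1e-12) continue;
    fb = em + slope * (gb - gm);
    arma::vec3 b = bfull;
    if (irls3(fb.memptr(), ab.memptr(), yb.memptr(), n, b, 25, 1e-6))
      out(r) = b(1);
  }
  return out;
}
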