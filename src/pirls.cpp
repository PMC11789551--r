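#define ARMA_WARN_LEVEL 1
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Penalized iteratively reweighted least squares for a binomial-count
// (or Bernoulli) GLMM with logit link and K crossed random-intercept
// factors.  The random-effect design is encoded as an N x K matrix of
// 0-based level codes; levels of factor k occupy the slice
// [off_k, off_k + nlev_k) of the stacked random-effect vector u.
//
// For fixed random-effect SDs sigma, the joint penalized log-likelihood
//   l(beta, u) = sum_i [ m_i eta_i - n_i log(1 + exp(eta_i)) ]
//                - 0.5 * sum_k |u_k|^2 / sigma_k^2
// is maximized over (beta, u) by damped Newton steps, and the Laplace
// deviance (-2 times the approximate marginal log-likelihood, binomial
// normalizing constant omitted) is evaluated at the joint mode:
//   dev = -2 l(beta_hat, u_hat) + log det(I + D Z'WZ),   D = diag(sigma^2).
//
// The log-determinant uses log det(D H_u) with H_u = Z'WZ + D^{-1}, which
// is numerically stable down to sigma ~ 1e-6 (the deviance then equals the
// plain GLM deviance, as it must at the boundary).

static const double PCLAMP = 1e-10;

// [[Rcpp::export]]
List pirls_binom(const arma::vec& m, const arma::vec& size,
                 const arma::mat& X, const arma::imat& G,
                 const arma::ivec& nlev, const arma::vec& sigma,
                 const arma::vec& v_init, int maxit, double tol,
                 bool want_vcov) {
  const int N = X.n_rows, p = X.n_cols, K = nlev.n_elem;
  arma::ivec off(K);
  int q = 0;
  for (int k = 0; k < K; ++k) { off[k] = q; q += nlev[k]; }
  const int dim = p + q;

  arma::vec pen(dim, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    double s2 = sigma[k] * sigma[k];
    for (int j = 0; j < nlev[k]; ++j) pen[p + off[k] + j] = 1.0 / s2;
  }

  arma::vec v = (int(v_init.n_elem) == dim) ? v_init
                                            : arma::vec(dim, arma::fill::zeros);

  // row pattern: p fixed-effect columns plus one indicator per factor
  const int nz = p + K;
  arma::uvec idx(nz);
  arma::vec val(nz);

  auto linpred = [&](const arma::vec& vv) {
    arma::vec eta = X * vv.head(p);
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < K; ++k)
        eta[i] += vv[p + off[k] + G(i, k)];
    return eta;
  };
  auto pll = [&](const arma::vec& vv, const arma::vec& eta) {
    double ll = 0.0;
    for (int i = 0; i < N; ++i) {
      double e = eta[i];
      // stable n*log(1+exp(eta))
      double lse = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
      ll += m[i] * e - size[i] * lse;
    }
    for (int j = p; j < dim; ++j) ll -= 0.5 * pen[j] * vv[j] * vv[j];
    return ll;
  };

  arma::vec eta = linpred(v);
  double f = pll(v, eta);
  arma::mat H(dim, dim);
  arma::vec grad(dim), mu(N), w(N);
  bool conv = false;

  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < N; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-eta[i]));
      pi = std::min(1.0 - PCLAMP, std::max(PCLAMP, pi));
      mu[i] = size[i] * pi;
      w[i] = size[i] * pi * (1.0 - pi);
    }
    grad.zeros();
    H.zeros();
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < p; ++j) { idx[j] = j; val[j] = X(i, j); }
      for (int k = 0; k < K; ++k) { idx[p + k] = p + off[k] + G(i, k); val[p + k] = 1.0; }
      double r = m[i] - mu[i];
      for (int a = 0; a < nz; ++a) {
        grad[idx[a]] += r * val[a];
        double wa = w[i] * val[a];
        for (int b = 0; b <= a; ++b) H(idx[a], idx[b]) += wa * val[b];
      }
    }
    for (int j = p; j < dim; ++j) {
      grad[j] -= pen[j] * v[j];
      H(j, j) += pen[j];
    }
    H = arma::symmatl(H);

    double gmax = arma::abs(grad).max();
    if (gmax < tol) { conv = true; break; }

    arma::vec step;
    bool ok = arma::solve(step, H, grad, arma::solve_opts::likely_sympd);
    if (!ok || !step.is_finite()) {
      return List::create(_["conv"] = false, _["reason"] = "solve_failed");
    }
    // damped Newton: halve until the penalized log-likelihood improves
    double t = 1.0;
    arma::vec vn;
    arma::vec etan;
    double fn = -std::numeric_limits<double>::infinity();
    for (int h = 0; h < 40; ++h) {
      vn = v + t * step;
      etan = linpred(vn);
      fn = pll(vn, etan);
      if (std::isfinite(fn) && fn >= f - 1e-12) break;
      t *= 0.5;
    }
    double df = fn - f;
    v = vn; eta = etan; f = fn;
    if (std::fabs(df) < 1e-12 && gmax < 1e-4) { conv = true; break; }
  }

  // Hessian blocks at the mode (recompute weights at final eta)
  for (int i = 0; i < N; ++i) {
    double pi = 1.0 / (1.0 + std::exp(-eta[i]));
    pi = std::min(1.0 - PCLAMP, std::max(PCLAMP, pi));
    mu[i] = size[i] * pi;
    w[i] = size[i] * pi * (1.0 - pi);
  }
  H.zeros();
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < p; ++j) { idx[j] = j; val[j] = X(i, j); }
    for (int k = 0; k < K; ++k) { idx[p + k] = p + off[k] + G(i, k); val[p + k] = 1.0; }
    for (int a = 0; a < nz; ++a) {
      double wa = w[i] * val[a];
      for (int b = 0; b <= a; ++b) H(idx[a], idx[b]) += wa * val[b];
    }
  }
  for (int j = p; j < dim; ++j) H(j, j) += pen[j];
  H = arma::symmatl(H);

  // log det(I + D Z'WZ) = log det(H_u) + sum_k nlev_k * log(sigma_k^2)
  double ld = 0.0;
  if (q > 0) {
    arma::mat Hu = H.submat(p, p, dim - 1, dim - 1);
    arma::mat R;
    if (!arma::chol(R, Hu))
      return List::create(_["conv"] = false, _["reason"] = "hessian_not_pd");
    ld = 2.0 * arma::accu(arma::log(R.diag()));
    for (int k = 0; k < K; ++k) ld += 2.0 * nlev[k] * std::log(sigma[k]);
  }

  double dev = -2.0 * f + ld;

  List out = List::create(
      _["conv"] = conv, _["reason"] = "", _["deviance"] = dev,
      _["beta"] = v.head(p), _["u"] = v.tail(q), _["v"] = v,
      _["eta"] = eta, _["logdet"] = ld);
  if (want_vcov) {
    arma::mat Hi;
    if (arma::inv_sympd(Hi, H)) out["vcov_beta"] = arma::mat(Hi.submat(0, 0, p - 1, p - 1));
    else out["vcov_beta"] = R_NilValue;
  }
  return out;
}
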