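// Blocked Gibbs sampler for the cross-classified log-normal Poisson model
//
//   y_i ~ Poisson(exp(theta_i))
//   theta_i ~ N(x_i' beta + sum_c u_{c, g_c(i)}, sigma2_obs)
//   beta_j ~ N(0, beta_prior_var)
//   u_{c,g} ~ N(0, sigma2_c)
//   sigma2 ~ half-Cauchy(0, A) via the inverse-gamma mixture
//            sigma2 | a ~ IG(1/2, 1/a), a ~ IG(1/2, 1/A^2),
//            or IG(eps, eps) when prior_type = 1.
//
// The latent log-mean theta is the only non-conjugate block; it is updated
// site-wise by a random-walk Metropolis step whose scale tracks the local
// curvature (exp(theta_i) + 1/sigma2_obs). Conditional on theta the model
// is a Gaussian linear mixed model and every other block is conjugate.
// All randomness flows through R's RNG so set.seed() governs the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  // 1 / Gamma(shape, rate); R::rgamma takes (shape, scale)
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export]]
List cc_poisson_gibbs(const arma::vec& y,
                      const arma::mat& X,
                      const List& group_idx,      // per component: 1-based index vec
                      const IntegerVector& n_groups,
                      const int n_iter,
                      const int burn_in,
                      const int thin,
                      const double beta_prior_var,
                      const int prior_type,       // 0 = half-Cauchy, 1 = IG(eps,eps)
                      const double scale_A,
                      const LogicalVector& store_u,
                      const List& const_cols,     // per component: 0-based column indices
                      const List& const_vals) {   // per component: G x k per-group values
  const int n = y.n_elem, p = X.n_cols, C = group_idx.size();
  const int n_kept = (n_iter - burn_in) / thin;

  std::vector<arma::uvec> gidx(C);
  std::vector<arma::vec> gcount(C);
  for (int c = 0; c < C; ++c) {
    IntegerVector gi = group_idx[c];
    arma::uvec v(n);
    for (int i = 0; i < n; ++i) v[i] = gi[i] - 1;
    gidx[c] = v;
    arma::vec cnt(n_groups[c], arma::fill::zeros);
    for (int i = 0; i < n; ++i) cnt[v[i]] += 1.0;
    gcount[c] = cnt;
  }

  // state
  arma::vec theta = arma::log(y + 0.5);
  arma::vec beta(p, arma::fill::zeros);
  beta[0] = std::log(arma::mean(y) + 0.5);
  std::vector<arma::vec> u(C);
  for (int c = 0; c < C; ++c) u[c] = arma::vec(n_groups[c], arma::fill::zeros);
  arma::vec sigma2(C + 1);
  sigma2.fill(0.5);                       // components, then observation-level
  arma::vec aux(C + 1, arma::fill::ones); // half-Cauchy mixing scales

  const arma::mat XtX = X.t() * X;
  arma::vec Xb = X * beta;
  arma::vec re(n, arma::fill::zeros);

  // output
  arma::mat beta_draws(n_kept, p);
  arma::mat sigma2_draws(n_kept, C + 1);
  std::vector<arma::mat> u_draws(C);
  std::vector<arma::vec> u_mean(C);
  for (int c = 0; c < C; ++c) {
    if (store_u[c]) u_draws[c] = arma::mat(n_kept, n_groups[c]);
    u_mean[c] = arma::vec(n_groups[c], arma::fill::zeros);
  }
  long long acc = 0, tries = 0;

  int kept = 0;
  for (int it = 1; it <= n_iter; ++it) {
    const double sig2e = sigma2[C];

    // latent log-means (site-wise Metropolis, cached exp(theta))
    re.zeros();
    for (int c = 0; c < C; ++c)
      for (int i = 0; i < n; ++i) re[i] += u[c][gidx[c][i]];
    const double inv_sig2e = 1.0 / sig2e;
    for (int i = 0; i < n; ++i) {
      const double m = Xb[i] + re[i];
      const double cur = theta[i];
      const double ecur = std::exp(cur > 30.0 ? 30.0 : cur);
      const double s = 2.4 / std::sqrt(ecur + inv_sig2e);
      const double prop = cur + s * R::norm_rand();
      if (prop > 30.0) continue;
      const double eprop = std::exp(prop);
      const double dcur = cur - m, dprop = prop - m;
      const double logr = y[i] * (prop - cur) - (eprop - ecur)
        - 0.5 * (dprop * dprop - dcur * dcur) * inv_sig2e;
      ++tries;
      if (std::log(R::unif_rand()) < logr) { theta[i] = prop; ++acc; }
    }

    // fixed effects (conjugate Gaussian given theta)
    {
      arma::vec r = theta - re;
      arma::mat A = XtX / sig2e;
      A.diag() += 1.0 / beta_prior_var;
      const arma::vec b = X.t() * r / sig2e;
      const arma::mat L = arma::chol(A, "lower");
      const arma::vec mean_b = arma::solve(arma::trimatu(L.t()),
                                           arma::solve(arma::trimatl(L), b));
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
      beta = mean_b + arma::solve(arma::trimatu(L.t()), z);
      Xb = X * beta;
    }

    // random intercepts (conjugate per group)
    for (int c = 0; c < C; ++c) {
      arma::vec r = theta - Xb;
      for (int c2 = 0; c2 < C; ++c2) {
        if (c2 == c) continue;
        for (int i = 0; i < n; ++i) r[i] -= u[c2][gidx[c2][i]];
      }
      arma::vec sums(n_groups[c], arma::fill::zeros);
      for (int i = 0; i < n; ++i) sums[gidx[c][i]] += r[i];
      for (int g = 0; g < n_groups[c]; ++g) {
        const double prec = gcount[c][g] / sig2e + 1.0 / sigma2[c];
        const double mu_g = (sums[g] / sig2e) / prec;
        u[c][g] = mu_g + R::norm_rand() / std::sqrt(prec);
      }
      // translation-group recentering (Liu-Sabatti): shift the component
      // mean into the intercept to break the intercept/u confounding
      const int G = n_groups[c];
      const double prec_m = G / sigma2[c] + 1.0 / beta_prior_var;
      const double mean_m = (arma::accu(u[c]) / sigma2[c]
                               - beta[0] / beta_prior_var) / prec_m;
      const double mshift = mean_m + R::norm_rand() / std::sqrt(prec_m);
      u[c] -= mshift;
      beta[0] += mshift;
      Xb += mshift;
      // analogous group moves along fixed-effect columns that are constant
      // within this component's groups (e.g. HRR-level covariates vs the
      // HRR intercepts, facility-constant dummies vs facility intercepts)
      const IntegerVector cc = const_cols[c];
      if (cc.size() > 0) {
        const arma::mat zv = const_vals[c];   // G x k
        for (int k = 0; k < cc.size(); ++k) {
          const int j = cc[k];
          const arma::vec z = zv.col(k);
          const double zz = arma::dot(z, z);
          if (zz <= 0) continue;
          const double prec_j = zz / sigma2[c] + 1.0 / beta_prior_var;
          const double mean_j = (arma::dot(z, u[c]) / sigma2[c]
                                   - beta[j] / beta_prior_var) / prec_j;
          const double mj = mean_j + R::norm_rand() / std::sqrt(prec_j);
          u[c] -= mj * z;
          beta[j] += mj;
          Xb += mj * X.col(j);
        }
      }
    }

    // variance components
    for (int c = 0; c < C; ++c) {
      const double ss = arma::dot(u[c], u[c]);
      if (prior_type == 0) {
        sigma2[c] = rinvgamma(0.5 + 0.5 * n_groups[c], 1.0 / aux[c] + 0.5 * ss);
        aux[c] = rinvgamma(1.0, 1.0 / (scale_A * scale_A) + 1.0 / sigma2[c]);
      } else {
        sigma2[c] = rinvgamma(0.001 + 0.5 * n_groups[c], 0.001 + 0.5 * ss);
      }
    }
    {
      re.zeros();
      for (int c = 0; c < C; ++c)
        for (int i = 0; i < n; ++i) re[i] += u[c][gidx[c][i]];
      const arma::vec resid = theta - Xb - re;
      const double ss = arma::dot(resid, resid);
      if (prior_type == 0) {
        sigma2[C] = rinvgamma(0.5 + 0.5 * n, 1.0 / aux[C] + 0.5 * ss);
        aux[C] = rinvgamma(1.0, 1.0 / (scale_A * scale_A) + 1.0 / sigma2[C]);
      } else {
        sigma2[C] = rinvgamma(0.001 + 0.5 * n, 0.001 + 0.5 * ss);
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_kept) {
      beta_draws.row(kept) = beta.t();
      sigma2_draws.row(kept) = sigma2.t();
      for (int c = 0; c < C; ++c) {
        if (store_u[c]) u_draws[c].row(kept) = u[c].t();
        u_mean[c] += u[c];
      }
      ++kept;
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  List u_out(C), u_mean_out(C);
  for (int c = 0; c < C; ++c) {
    u_out[c] = store_u[c] ? wrap(u_draws[c]) : R_NilValue;
    u_mean_out[c] = wrap(arma::vec(u_mean[c] / std::max(kept, 1)));
  }
  return List::create(
    _["beta"] = beta_draws,
    _["sigma2"] = sigma2_draws,
    _["u"] = u_out,
    _["u_mean"] = u_mean_out,
    _["accept_rate"] = tries > 0 ? double(acc) / double(tries) : NA_REAL,
    _["n_kept"] = kept);
}
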