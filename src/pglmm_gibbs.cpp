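// Gibbs sampler core for Bayesian phylogenetic generalized linear mixed
// models. Gaussian responses use blocked Gibbs: all location effects are
// drawn jointly from their multivariate-normal full conditional and
// variance components from inverse-gamma full conditionals under a
// parameter-expanded prior (working scale parameter alpha with N(0, 1e3)
// prior; base variance IG with scale 1, dof 1). Bernoulli responses use
// the latent-variable representation with residual variance fixed at
// pi^2/3, single-site slice updates for the latents, and a Cauchy prior
// on fixed effects represented as a normal-inverse-gamma scale mixture.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// log density (up to a constant) of one Bernoulli latent given its
// Gaussian prior N(eta, phi) and observation y
static inline double latent_logf(double l, double y, double eta, double phi) {
  return y * l - softplus(l) - (l - eta) * (l - eta) / (2.0 * phi);
}

// Neal's slice sampler with stepping out, for one latent value
static double slice_latent(double l0, double y, double eta, double phi) {
  const double w = 2.0;
  const int m = 50;
  double z = latent_logf(l0, y, eta, phi) - R::rexp(1.0);
  double u = R::runif(0.0, 1.0);
  double L = l0 - w * u;
  double Rr = L + w;
  int j = std::floor(R::runif(0.0, 1.0) * m);
  int k = m - 1 - j;
  while (j-- > 0 && latent_logf(L, y, eta, phi) > z) L -= w;
  while (k-- > 0 && latent_logf(Rr, y, eta, phi) > z) Rr += w;
  for (int it = 0; it < 200; ++it) {
    double l1 = R::runif(L, Rr);
    if (latent_logf(l1, y, eta, phi) > z) return l1;
    if (l1 < l0) L = l1; else Rr = l1;
  }
  return l0;  // degenerate shrinkage; keep current value
}

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".pglmm_gibbs_cpp")]]
Rcpp::List pglmm_gibbs_cpp(const arma::vec& y, const arma::mat& X,
                           const arma::uvec& sp, int q,
                           const arma::mat& Sigma_inv,
                           bool has_phylo, bool has_species,
                           int family,            // 0 gaussian, 1 bernoulli
                           double sigma_e_fixed,  // <= 0: estimate
                           double fixed_sigma2_p, // <= 0: estimate (PX)
                           double fixed_sigma2_s,
                           double beta_prior_var, // gaussian fixed effects
                           double px_alpha_var, double px_nu, double px_V,
                           double resid_nu, double resid_V,
                           int n_iter, int burn, int thin) {
  const int n = y.n_elem, p = X.n_cols;
  const int d = p + q * (has_phylo ? 1 : 0) + q * (has_species ? 1 : 0);
  const int off_p = p;
  const int off_s = p + (has_phylo ? q : 0);
  const double phi_logistic = M_PI * M_PI / 3.0;

  // fixed pieces of the cross-products
  mat XtX = X.t() * X;
  mat XtZ(p, q, fill::zeros);
  vec counts(q, fill::zeros);
  for (int i = 0; i < n; ++i) {
    XtZ.col(sp[i]) += X.row(i).t();
    counts[sp[i]] += 1.0;
  }

  // state
  vec l = y;  // latent response (equals y for gaussian)
  if (family == 1) l = 2.0 * y - 1.0;
  vec beta(p, fill::zeros);
  vec u_p(q, fill::zeros), u_s(q, fill::zeros);
  double alpha_p = 1.0, alpha_s = 1.0;
  double st_p = 1.0, st_s = 1.0;  // working-scale base variances
  bool est_p = has_phylo && fixed_sigma2_p <= 0.0;
  bool est_s = has_species && fixed_sigma2_s <= 0.0;
  if (has_phylo && !est_p) st_p = fixed_sigma2_p;
  if (has_species && !est_s) st_s = fixed_sigma2_s;
  double sigma_e2 = (sigma_e_fixed > 0.0) ? sigma_e_fixed
                                          : std::max(1e-6, var(l));
  if (family == 1) sigma_e2 = phi_logistic;
  vec psi(p);
  psi.fill(beta_prior_var);  // per-coefficient prior variance

  const int n_keep = (n_iter - burn) / thin;
  int n_par = p + 3;  // betas + sigma2_p + sigma2_s + sigma2_e
  mat draws(n_keep, n_par);
  int keep = 0;

  vec Xtl = X.t() * l;
  vec Ztl(q, fill::zeros);
  for (int i = 0; i < n; ++i) Ztl[sp[i]] += l[i];

  mat P(d, d);
  vec rhs(d), mu(d), theta(d), z(d);

  for (int iter = 0; iter < n_iter; ++iter) {
    // ---- joint update of (beta, u_p, u_s) -------------------------------
    double ie = 1.0 / sigma_e2;
    P.zeros();
    P.submat(0, 0, p - 1, p - 1) = ie * XtX;
    for (int k = 0; k < p; ++k) P(k, k) += 1.0 / psi[k];
    rhs.zeros();
    rhs.subvec(0, p - 1) = ie * Xtl;
    if (has_phylo) {
      P.submat(0, off_p, p - 1, off_p + q - 1) = (alpha_p * ie) * XtZ;
      P.submat(off_p, 0, off_p + q - 1, p - 1) =
          P.submat(0, off_p, p - 1, off_p + q - 1).t();
      P.submat(off_p, off_p, off_p + q - 1, off_p + q - 1) = Sigma_inv / st_p;
      for (int k = 0; k < q; ++k)
        P(off_p + k, off_p + k) += alpha_p * alpha_p * ie * counts[k];
      rhs.subvec(off_p, off_p + q - 1) = (alpha_p * ie) * Ztl;
    }
    if (has_species) {
      P.submat(0, off_s, p - 1, off_s + q - 1) = (alpha_s * ie) * XtZ;
      P.submat(off_s, 0, off_s + q - 1, p - 1) =
          P.submat(0, off_s, p - 1, off_s + q - 1).t();
      for (int k = 0; k < q; ++k)
        P(off_s + k, off_s + k) = alpha_s * alpha_s * ie * counts[k] + 1.0 / st_s;
      rhs.subvec(off_s, off_s + q - 1) = (alpha_s * ie) * Ztl;
      if (has_phylo) {
        double c = alpha_p * alpha_s * ie;
        for (int k = 0; k < q; ++k) {
          P(off_p + k, off_s + k) = c * counts[k];
          P(off_s + k, off_p + k) = c * counts[k];
        }
      }
    }
    mat R;
    if (!chol(R, P)) Rcpp::stop("full-conditional precision not positive definite");
    mu = solve(trimatu(R), solve(trimatl(R.t()), rhs));
    for (int k = 0; k < d; ++k) z[k] = R::norm_rand();
    theta = mu + solve(trimatu(R), z);
    beta = theta.subvec(0, p - 1);
    if (has_phylo) u_p = theta.subvec(off_p, off_p + q - 1);
    if (has_species) u_s = theta.subvec(off_s, off_s + q - 1);

    vec xb = X * beta;
    vec zup(n, fill::zeros), zus(n, fill::zeros);
    if (has_phylo) for (int i = 0; i < n; ++i) zup[i] = u_p[sp[i]];
    if (has_species) for (int i = 0; i < n; ++i) zus[i] = u_s[sp[i]];

    // ---- parameter-expansion updates -----------------------------------
    if (est_p) {
      vec r = l - xb - alpha_s * zus;
      double prec = dot(zup, zup) * ie + 1.0 / px_alpha_var;
      double m = dot(zup, r) * ie / prec;
      alpha_p = m + R::norm_rand() / std::sqrt(prec);
      double quad = as_scalar(u_p.t() * Sigma_inv * u_p);
      st_p = rinvgamma((px_nu + q) / 2.0, (px_nu * px_V + quad) / 2.0);
    }
    if (est_s) {
      vec r = l - xb - alpha_p * zup;
      double prec = dot(zus, zus) * ie + 1.0 / px_alpha_var;
      double m = dot(zus, r) * ie / prec;
      alpha_s = m + R::norm_rand() / std::sqrt(prec);
      st_s = rinvgamma((px_nu + q) / 2.0, (px_nu * px_V + dot(u_s, u_s)) / 2.0);
    }
    double s2p = has_phylo ? alpha_p * alpha_p * st_p : 0.0;
    double s2s = has_species ? alpha_s * alpha_s * st_s : 0.0;

    vec eta = xb + alpha_p * zup + alpha_s * zus;

    // ---- residual variance / latents -----------------------------------
    if (family == 0) {
      if (sigma_e_fixed <= 0.0) {
        vec e = l - eta;
        sigma_e2 = rinvgamma((resid_nu + n) / 2.0,
                             (resid_nu * resid_V + dot(e, e)) / 2.0);
      }
    } else {
      for (int i = 0; i < n; ++i)
        l[i] = slice_latent(l[i], y[i], eta[i], phi_logistic);
      Xtl = X.t() * l;
      Ztl.zeros();
      for (int i = 0; i < n; ++i) Ztl[sp[i]] += l[i];
      // Cauchy prior via scale mixture; scale = pi^2/3 + current random-
      // effect variance, re-evaluated each iteration
      double gam = phi_logistic + s2p + s2s;
      for (int k = 0; k < p; ++k)
        psi[k] = rinvgamma(1.0, (beta[k] * beta[k] + gam * gam) / 2.0);
    }

    // ---- record ---------------------------------------------------------
    if (iter >= burn && (iter - burn) % thin == 0 && keep < n_keep) {
      for (int k = 0; k < p; ++k) draws(keep, k) = beta[k];
      draws(keep, p) = s2p;
      draws(keep, p + 1) = s2s;
      draws(keep, p + 2) = sigma_e2;
      ++keep;
    }
    if (iter % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(Rcpp::Named("draws") = draws,
                            Rcpp::Named("n_kept") = keep);
}
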