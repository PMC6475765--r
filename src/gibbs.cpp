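// Gibbs sampler for the hierarchical model of regional annualized change:
//   y[i,r] = alpha[g(i),r] + beta[g(i),r] * x[i] + eps,  eps ~ N(0, sigma)
//   alpha[g,.] ~ N(mu_a[g], tau_a[g]),  beta[g,.] ~ N(mu_b[g], tau_b[g])
//   mu ~ N(0, s_mu), tau/sigma ~ half-N(0, s_tau)
// Conjugate normal block updates for (alpha, beta) and mu; slice sampling
// on the log scale for the half-Normal-prior scales (non-conjugate).
// The likelihood enters only through per-group sufficient statistics
// (1'Y, x'Y, sum y^2, n, sum x, sum x^2), all precomputed, so each
// iteration costs O(G * R). Uses R's RNG so chains are reproducible from
// set.seed() on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// numerical guards: scales confined to [1e-8, 1e6] so the slice cannot
// wander to -inf on degenerate (noise-free) data
static const double LOG_SCALE_MIN = std::log(1e-8);
static const double LOG_SCALE_MAX = std::log(1e6);

// log posterior of eta = log(scale) for `nobs` normal deviations with
// summed squares `ssd`, half-Normal(0, prior_scale) prior, + Jacobian
static double scale_logpost(double eta, double nobs, double ssd,
                            double prior_scale) {
  double s2 = std::exp(2.0 * eta);
  return -nobs * eta - ssd / (2.0 * s2)
         - s2 / (2.0 * prior_scale * prior_scale) + eta;
}

// univariate slice sampler (Neal 2003, stepping out + shrinkage)
static double slice_scale(double cur, double nobs, double ssd,
                          double prior_scale) {
  double eta = std::clamp(std::log(cur), LOG_SCALE_MIN, LOG_SCALE_MAX);
  double f0 = scale_logpost(eta, nobs, ssd, prior_scale);
  if (!std::isfinite(f0))
    Rcpp::stop("non-finite log-density in scale update (ssd=%g)", ssd);
  double logy = f0 - R::rexp(1.0);
  const double w = 1.0;
  const int m = 50;
  double L = eta - w * R::runif(0.0, 1.0);
  double Rr = L + w;
  int j = std::floor(m * R::runif(0.0, 1.0));
  int k = m - 1 - j;
  while (j-- > 0 && L > LOG_SCALE_MIN &&
         scale_logpost(L, nobs, ssd, prior_scale) > logy)
    L -= w;
  while (k-- > 0 && Rr < LOG_SCALE_MAX &&
         scale_logpost(Rr, nobs, ssd, prior_scale) > logy)
    Rr += w;
  L = std::max(L, LOG_SCALE_MIN);
  Rr = std::min(Rr, LOG_SCALE_MAX);
  for (int it = 0; it < 200; ++it) {
    double prop = R::runif(L, Rr);
    if (scale_logpost(prop, nobs, ssd, prior_scale) > logy)
      return std::exp(prop);
    if (prop < eta) L = prop; else Rr = prop;
  }
  return std::exp(eta);  // shrinkage exhausted: keep current value
}

// conjugate normal draw for a group hypermean
static double draw_hypermean(const rowvec& theta, double tau,
                             double prior_sd) {
  double R_ = theta.n_elem;
  double prec = R_ / (tau * tau) + 1.0 / (prior_sd * prior_sd);
  double mean = accu(theta) / (tau * tau) / prec;
  return mean + R::rnorm(0.0, 1.0) / std::sqrt(prec);
}

// draw (alpha, beta) rows for one group from the 2x2 conjugate posterior
static void draw_effect_block(rowvec& a_row, rowvec& b_row,
                              const rowvec& c0, const rowvec& c1,
                              double n1, double sx, double sxx,
                              double sig, double mu_a, double tau_a,
                              double mu_b, double tau_b) {
  const int R_ = c0.n_elem;
  double is2 = 1.0 / (sig * sig);
  mat A(2, 2);
  A(0, 0) = is2 * n1 + 1.0 / (tau_a * tau_a);
  A(0, 1) = A(1, 0) = is2 * sx;
  A(1, 1) = is2 * sxx + 1.0 / (tau_b * tau_b);
  mat B(2, R_);
  B.row(0) = is2 * c0 + mu_a / (tau_a * tau_a);
  B.row(1) = is2 * c1 + mu_b / (tau_b * tau_b);
  mat M = solve(A, B, solve_opts::likely_sympd);
  mat Lc = chol(inv_sympd(A), "lower");
  mat Z(2, R_);
  for (uword z = 0; z < Z.n_elem; ++z) Z(z) = R::rnorm(0.0, 1.0);
  mat D = M + Lc * Z;
  a_row = D.row(0);
  b_row = D.row(1);
}

// [[Rcpp::export]]
Rcpp::List gibbs_chain(const arma::mat& y, const arma::vec& x,
                       const arma::uvec& g, int n_groups,
                       int n_iter, int burn_in, int thin,
                       const Rcpp::List& init,
                       double hyper_mean_scale, double hyper_sd_scale,
                       double resid_sd_scale, bool per_region_sigma) {
  const int n = y.n_rows, R_ = y.n_cols, G = n_groups;
  if (thin < 1) Rcpp::stop("thin must be >= 1");
  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) Rcpp::stop("no draws retained: check schedule");

  mat alpha = Rcpp::as<mat>(init["alpha"]);  // G x R
  mat beta  = Rcpp::as<mat>(init["beta"]);
  vec mu_a  = Rcpp::as<vec>(init["mu_alpha"]);
  vec tau_a = Rcpp::as<vec>(init["tau_alpha"]);
  vec mu_b  = Rcpp::as<vec>(init["mu_beta"]);
  vec tau_b = Rcpp::as<vec>(init["tau_beta"]);
  vec sigma = Rcpp::as<vec>(init["sigma"]);  // length 1 or R

  // fixed per-group sufficient statistics
  mat c0(G, R_), c1(G, R_), ssy(G, R_);
  vec sum1(G), sumx(G), sumxx(G);
  for (int k = 0; k < G; ++k) {
    uvec ik = find(g == (unsigned) k);
    if (ik.n_elem < 2)
      Rcpp::stop("degenerate design: group %d has < 2 subjects", k + 1);
    mat Yg = y.rows(ik);
    vec xg = x.elem(ik);
    c0.row(k) = sum(Yg, 0);
    c1.row(k) = xg.t() * Yg;
    ssy.row(k) = sum(square(Yg), 0);
    sum1(k) = xg.n_elem;
    sumx(k) = accu(xg);
    sumxx(k) = accu(xg % xg);
  }

  mat alpha_out(n_keep, G * R_), beta_out(n_keep, G * R_);
  mat mu_a_out(n_keep, G), tau_a_out(n_keep, G);
  mat mu_b_out(n_keep, G), tau_b_out(n_keep, G);
  mat sigma_out(n_keep, sigma.n_elem);

  rowvec a_row(R_), b_row(R_);
  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- (alpha, beta) block per group ---
    for (int k = 0; k < G; ++k) {
      if (!per_region_sigma) {
        draw_effect_block(a_row, b_row, c0.row(k), c1.row(k), sum1(k),
                          sumx(k), sumxx(k), sigma(0), mu_a(k), tau_a(k),
                          mu_b(k), tau_b(k));
        alpha.row(k) = a_row;
        beta.row(k) = b_row;
      } else {
        rowvec one(1);
        for (int r = 0; r < R_; ++r) {
          rowvec a1(1), b1(1);
          rowvec c0r = c0.submat(k, r, k, r);
          rowvec c1r = c1.submat(k, r, k, r);
          draw_effect_block(a1, b1, c0r, c1r, sum1(k), sumx(k),
                            sumxx(k), sigma(r), mu_a(k), tau_a(k),
                            mu_b(k), tau_b(k));
          alpha(k, r) = a1(0);
          beta(k, r) = b1(0);
        }
      }
    }

    // --- group hypermeans and hyper-sds ---
    for (int k = 0; k < G; ++k) {
      mu_a(k) = draw_hypermean(alpha.row(k), tau_a(k), hyper_mean_scale);
      mu_b(k) = draw_hypermean(beta.row(k), tau_b(k), hyper_mean_scale);
      tau_a(k) = slice_scale(tau_a(k), R_,
                             accu(square(alpha.row(k) - mu_a(k))),
                             hyper_sd_scale);
      tau_b(k) = slice_scale(tau_b(k), R_,
                             accu(square(beta.row(k) - mu_b(k))),
                             hyper_sd_scale);
    }

    // --- residual sd via closed-form per-(group, ROI) residual SS:
    //     sum_i (y - a - b x)^2
    //       = ssy - 2 a c0 - 2 b c1 + a^2 n + 2 a b Sx + b^2 Sxx ---
    rowvec ss_region(R_, fill::zeros);
    for (int k = 0; k < G; ++k) {
      rowvec a = alpha.row(k), b = beta.row(k);
      ss_region += ssy.row(k) - 2.0 * (a % c0.row(k))
                 - 2.0 * (b % c1.row(k)) + sum1(k) * square(a)
                 + 2.0 * sumx(k) * (a % b) + sumxx(k) * square(b);
    }
    ss_region.clamp(0.0, datum::inf);  // guard tiny negative cancellation
    if (!per_region_sigma) {
      sigma(0) = slice_scale(sigma(0), (double) n * R_, accu(ss_region),
                             resid_sd_scale);
    } else {
      for (int r = 0; r < R_; ++r)
        sigma(r) = slice_scale(sigma(r), (double) n, ss_region(r),
                               resid_sd_scale);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      alpha_out.row(keep) = vectorise(alpha).t();  // (g,r) at r*G+g
      beta_out.row(keep) = vectorise(beta).t();
      mu_a_out.row(keep) = mu_a.t();
      tau_a_out.row(keep) = tau_a.t();
      mu_b_out.row(keep) = mu_b.t();
      tau_b_out.row(keep) = tau_b.t();
      sigma_out.row(keep) = sigma.t();
      ++keep;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("alpha") = alpha_out,
    Rcpp::Named("beta") = beta_out,
    Rcpp::Named("mu_alpha") = mu_a_out,
    Rcpp::Named("tau_alpha") = tau_a_out,
    Rcpp::Named("mu_beta") = mu_b_out,
    Rcpp::Named("tau_beta") = tau_b_out,
    Rcpp::Named("sigma") = sigma_out);
}
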