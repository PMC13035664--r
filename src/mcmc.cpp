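// MCMC cores for the manifest, hierarchical, and two-condition contrast
// models under the inverse Wishart (conjugate Gibbs), scaled inverse
// Wishart (Gibbs with inverse-gamma mixing variables), and LKJ
// (Metropolis-within-Gibbs on partial correlations and log scales) priors.
//
// All randomness goes through R's RNG (R::*_rand / R::r*), so draws are
// bit-identical for a fixed R seed.

#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// Sigma ~ Inverse Wishart(Psi, df) via Bartlett decomposition of the
// Wishart(df, Psi^{-1}) draw. Requires df > J - 1 and Psi positive definite.
static arma::mat riwish(double df, const arma::mat& Psi) {
  const int J = Psi.n_rows;
  arma::mat C = arma::chol(arma::symmatu(Psi));      // Psi = C' C (C upper)
  arma::mat B = arma::inv(arma::trimatu(C));         // B B' = Psi^{-1}
  arma::mat A(J, J, arma::fill::zeros);
  for (int i = 0; i < J; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat BA = B * A;
  arma::mat W = BA * BA.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// build the lower Cholesky factor of a correlation matrix from canonical
// partial correlations z (lower triangle, entries in (-1, 1))
static arma::mat chol_from_z(const arma::mat& Z) {
  const int J = Z.n_rows;
  arma::mat L(J, J, arma::fill::zeros);
  L(0, 0) = 1.0;
  for (int i = 1; i < J; ++i) {
    double sumsq = 0.0;
    for (int j = 0; j < i; ++j) {
      L(i, j) = Z(i, j) * std::sqrt(std::max(1.0 - sumsq, 0.0));
      sumsq += L(i, j) * L(i, j);
    }
    L(i, i) = std::sqrt(std::max(1.0 - sumsq, 1e-300));
  }
  return L;
}

// recover partial correlations from a lower Cholesky factor (for inits)
static arma::mat z_from_chol(const arma::mat& L) {
  const int J = L.n_rows;
  arma::mat Z(J, J, arma::fill::zeros);
  for (int i = 1; i < J; ++i) {
    double sumsq = 0.0;
    for (int j = 0; j < i; ++j) {
      double denom = std::sqrt(std::max(1.0 - sumsq, 1e-12));
      Z(i, j) = L(i, j) / denom;
      sumsq += L(i, j) * L(i, j);
    }
  }
  return Z;
}

// [[Rcpp::export]]
arma::cube lkj_onion_cpp(int n_draws, int J, double eta) {
  arma::cube out(J, J, n_draws);
  arma::mat Z(J, J, arma::fill::zeros);
  for (int d = 0; d < n_draws; ++d) {
    for (int i = 1; i < J; ++i) {
      for (int j = 0; j < i; ++j) {
        double a = eta + (J - 2.0 - j) / 2.0;
        Z(i, j) = 2.0 * R::rbeta(a, a) - 1.0;
      }
    }
    arma::mat L = chol_from_z(Z);
    out.slice(d) = L * L.t();
  }
  return out;
}

static double scale_logprior(double x, int fam, double p1, double p2) {
  if (x <= 0.0) return R_NegInf;
  switch (fam) {
    case 1: return M_LN2 + R::dt(x / p2, p1, 1) - std::log(p2);  // half-t(df p1, scale p2)
    case 2: return M_LN2 + R::dnorm(x, 0.0, p1, 1);              // half-normal(sd p1)
    case 3: return M_LN2 + R::dcauchy(x, 0.0, p1, 1);            // half-Cauchy(scale p1)
    case 4: return R::dexp(x, p1, 1);                            // exponential(scale p1)
    case 5: return R::dgamma(x, p1, p2, 1);                      // gamma(shape p1, scale p2)
    case 6: return R::dlnorm(x, p1, p2, 1);                      // lognormal(meanlog, sdlog)
    case 7: return x <= p1 ? -std::log(p1) : R_NegInf;           // uniform(0, p1)
  }
  return R_NegInf;
}

// unnormalized log target of the LKJ block: LKJ(eta) on rho expressed in
// unconstrained partial-correlation coordinates y (Jacobian included, so the
// per-entry contribution is a_j * log(1 - z^2)), scale priors on sigma with
// the log-scale Jacobian, and the multivariate-normal likelihood of the
// centered true scores through Stheta = sum_i (theta_i - mu)(theta_i - mu)'.
static double lkj_log_target(const arma::mat& Z, const arma::mat& L,
                             const arma::vec& sigma, double eta,
                             const arma::ivec& fam, const arma::mat& fam_par,
                             const arma::mat& Stheta, double I_eff) {
  const int J = L.n_rows;
  double lp = 0.0;
  for (int i = 1; i < J; ++i) {
    for (int j = 0; j < i; ++j) {
      double a = eta + (J - 2.0 - j) / 2.0;
      double om = 1.0 - Z(i, j) * Z(i, j);
      if (om <= 0.0) return R_NegInf;
      lp += a * std::log(om);
    }
  }
  for (int j = 0; j < J; ++j) {
    lp += scale_logprior(sigma(j), fam(j), fam_par(j, 0), fam_par(j, 1));
    lp += std::log(sigma(j));  // Jacobian of the log-scale random walk
  }
  if (!std::isfinite(lp)) return R_NegInf;
  if (I_eff > 0.0) {
    double logdet_half = arma::accu(arma::log(sigma)) +
      arma::accu(arma::log(L.diag()));
    arma::mat M = Stheta / (sigma * sigma.t());
    arma::mat Bm = arma::solve(arma::trimatl(L), M);
    arma::mat Cm = arma::solve(arma::trimatl(L), Bm.t());
    lp += -I_eff * logdet_half - 0.5 * arma::trace(Cm);
  }
  return lp;
}

// [[Rcpp::export]]
List run_mcmc_cpp(const arma::mat& m, const arma::mat& neff,
                  const arma::mat& abar, const arma::mat& ssw,
                  const arma::vec& ntrials, const arma::mat& ncond,
                  int design, int prior_type,
                  double v_or_eta, const arma::mat& S_iw, const arma::vec& s_vec,
                  const arma::ivec& fam, const arma::mat& fam_par,
                  const arma::vec& mu_prior_var, bool fix_mu, const arma::vec& mu_fixed,
                  double tau_a, const arma::vec& tau_b,
                  const arma::vec& alpha_prior_var,
                  int n_burn, int n_keep, bool likelihood_on,
                  double target_accept, bool store_theta,
                  const List& init) {
  const int I = m.n_rows, J = m.n_cols;
  const int npair = J * (J - 1) / 2;
  const double I_eff = likelihood_on ? static_cast<double>(I) : 0.0;

  // state
  arma::mat theta = as<arma::mat>(init["theta"]);
  arma::vec mu = fix_mu ? mu_fixed : as<arma::vec>(init["mu"]);
  arma::vec tau2 = as<arma::vec>(init["tau2"]);
  arma::mat Sigma = as<arma::mat>(init["Sigma"]);
  arma::mat alpha(I, J, arma::fill::zeros);
  if (design == 2) alpha = abar;

  // LKJ state
  arma::vec sigma_lkj(J, arma::fill::ones);
  arma::mat Z(J, J, arma::fill::zeros), Lc(J, J, arma::fill::eye);
  double step_rho = 2.38 / std::sqrt(std::max(npair, 1)) * 0.5;
  arma::vec step_sig(J, arma::fill::value(0.3));
  double acc_rho = 0.0;
  arma::vec acc_sig(J, arma::fill::zeros);
  long n_prop = 0;
  if (prior_type == 2) {
    arma::vec sd0 = arma::sqrt(Sigma.diag());
    sigma_lkj = sd0;
    arma::mat rho0 = Sigma / (sd0 * sd0.t());
    rho0.diag().ones();
    arma::mat L0 = arma::chol(arma::symmatu(rho0), "lower");
    Z = z_from_chol(L0);
    Z = arma::clamp(Z, -0.999, 0.999);
    Lc = chol_from_z(Z);
    Sigma = (sigma_lkj * sigma_lkj.t()) % (Lc * Lc.t());
  }
  arma::mat Siginv = arma::inv_sympd(arma::symmatu(Sigma));

  const bool balanced = likelihood_on && design != 0 &&
    arma::all(arma::vectorise(arma::abs(neff.each_row() - neff.row(0))) < 1e-12);
  arma::rowvec neff0 = (design != 0 && I > 0) ? neff.row(0) : arma::rowvec(J, arma::fill::zeros);

  // storage
  arma::mat keep_mu(n_keep, J), keep_sigma(n_keep, J), keep_tau(n_keep, J),
            keep_rho(n_keep, npair);
  arma::mat theta_mean(I, J, arma::fill::zeros);
  arma::mat alpha_mean(I, J, arma::fill::zeros);
  arma::cube theta_draws;
  if (store_theta) theta_draws.set_size(I, J, n_keep);

  const int n_iter = n_burn + n_keep;
  for (int t = 1; t <= n_iter; ++t) {
    // --- theta | Sigma, mu, tau ------------------------------------------
    if (likelihood_on && design != 0) {
      if (balanced) {
        arma::vec w = neff0.t() / tau2;
        arma::mat Lambda = Siginv + arma::diagmat(w);
        arma::mat U = arma::chol(arma::symmatu(Lambda));  // Lambda = U'U
        arma::vec base = Siginv * mu;
        arma::mat H = m.each_row() % w.t();               // I x J
        H.each_row() += base.t();
        arma::mat Zn(J, I);
        for (int i = 0; i < I; ++i) Zn.col(i) = rnorm_vec(J);
        // theta' = U^{-1} (U^{-T} H' + Z): one Cholesky, two triangular solves
        arma::mat tmp = arma::solve(arma::trimatl(U.t()), H.t());
        theta = arma::solve(arma::trimatu(U), tmp + Zn).t();
      } else {
        arma::vec base = Siginv * mu;
        for (int i = 0; i < I; ++i) {
          arma::vec w = neff.row(i).t() / tau2;
          arma::mat Lambda = Siginv + arma::diagmat(w);
          arma::mat U = arma::chol(arma::symmatu(Lambda));
          arma::vec h = base + m.row(i).t() % w;
          arma::vec tmp = arma::solve(arma::trimatl(U.t()), h);
          theta.row(i) = arma::solve(arma::trimatu(U), tmp + rnorm_vec(J)).t();
        }
      }
    }

    // --- alpha | theta, tau (contrast intercepts) ------------------------
    if (likelihood_on && design == 2) {
      for (int j = 0; j < J; ++j) {
        double pv = 1.0 / alpha_prior_var(j);
        for (int i = 0; i < I; ++i) {
          double prec = 2.0 * ncond(i, j) / tau2(j) + pv;
          double mean = (2.0 * ncond(i, j) / tau2(j)) * abar(i, j) / prec;
          alpha(i, j) = mean + R::norm_rand() / std::sqrt(prec);
        }
      }
    }

    // --- mu | theta, Sigma ------------------------------------------------
    if (!fix_mu) {
      arma::mat P = arma::diagmat(1.0 / mu_prior_var);
      arma::vec h(J, arma::fill::zeros);
      if (I_eff > 0.0) {
        P += I_eff * Siginv;
        h = Siginv * arma::sum(theta, 0).t();
      }
      arma::mat U = arma::chol(arma::symmatu(P));
      arma::vec mean_mu = arma::solve(arma::symmatu(P), h);
      mu = mean_mu + arma::solve(arma::trimatu(U), rnorm_vec(J));
    }

    // --- tau^2 | theta, alpha --------------------------------------------
    if (likelihood_on && design != 0) {
      for (int j = 0; j < J; ++j) {
        double ss = 0.0;
        if (design == 1) {
          for (int i = 0; i < I; ++i) {
            double d = m(i, j) - theta(i, j);
            ss += ssw(i, j) + neff(i, j) * d * d;
          }
        } else {
          for (int i = 0; i < I; ++i) {
            double da = abar(i, j) - alpha(i, j);
            double dt = theta(i, j) - m(i, j);
            ss += ssw(i, j) + ncond(i, j) * (2.0 * da * da + 0.5 * dt * dt);
          }
        }
        double shape = tau_a + 0.5 * ntrials(j);
        double rate = tau_b(j) + 0.5 * ss;
        tau2(j) = 1.0 / R::rgamma(shape, 1.0 / rate);
      }
    }

    // --- Sigma ------------------------------------------------------------
    arma::mat Stheta(J, J, arma::fill::zeros);
    if (I_eff > 0.0) {
      arma::mat cen = theta.each_row() - mu.t();
      Stheta = cen.t() * cen;
    }

    if (prior_type == 0) {                      // inverse Wishart
      Sigma = riwish(v_or_eta + I_eff, S_iw + Stheta);
      Siginv = arma::inv_sympd(arma::symmatu(Sigma));
    } else if (prior_type == 1) {               // scaled inverse Wishart
      arma::vec alph(J);
      for (int j = 0; j < J; ++j) {
        double shape = (v_or_eta + J) / 2.0;
        double rate = v_or_eta * Siginv(j, j) + 1.0 / (s_vec(j) * s_vec(j));
        alph(j) = 1.0 / R::rgamma(shape, 1.0 / rate);
      }
      arma::mat Psi = 2.0 * v_or_eta * arma::diagmat(1.0 / alph) + Stheta;
      Sigma = riwish(v_or_eta + J - 1.0 + I_eff, Psi);
      Siginv = arma::inv_sympd(arma::symmatu(Sigma));
    } else {                                    // LKJ: MH blocks
      double cur = lkj_log_target(Z, Lc, sigma_lkj, v_or_eta, fam, fam_par,
                                  Stheta, I_eff);
      // joint random walk on the unconstrained partial correlations
      {
        arma::mat Zprop = Z;
        for (int i = 1; i < J; ++i) {
          for (int j = 0; j < i; ++j) {
            double y = std::atanh(Z(i, j)) + step_rho * R::norm_rand();
            Zprop(i, j) = std::tanh(y);
          }
        }
        arma::mat Lprop = chol_from_z(Zprop);
        double prop = lkj_log_target(Zprop, Lprop, sigma_lkj, v_or_eta, fam,
                                     fam_par, Stheta, I_eff);
        double lr = prop - cur;
        double ap = std::isfinite(lr) ? std::min(1.0, std::exp(lr)) : 0.0;
        if (R::unif_rand() < ap) { Z = Zprop; Lc = Lprop; cur = prop; }
        if (t <= n_burn) {
          step_rho *= std::exp(std::pow((double)t, -0.6) * (ap - target_accept));
        } else {
          acc_rho += ap;
        }
      }
      // log-scale random walk on each sigma_j
      for (int j = 0; j < J; ++j) {
        arma::vec sprop = sigma_lkj;
        sprop(j) = sigma_lkj(j) * std::exp(step_sig(j) * R::norm_rand());
        double prop = lkj_log_target(Z, Lc, sprop, v_or_eta, fam, fam_par,
                                     Stheta, I_eff);
        double lr = prop - cur;
        double ap = std::isfinite(lr) ? std::min(1.0, std::exp(lr)) : 0.0;
        if (R::unif_rand() < ap) { sigma_lkj = sprop; cur = prop; }
        if (t <= n_burn) {
          step_sig(j) *= std::exp(std::pow((double)t, -0.6) * (ap - target_accept));
        } else {
          acc_sig(j) += ap;
        }
      }
      if (t > n_burn) ++n_prop;
      arma::mat rho = Lc * Lc.t();
      Sigma = (sigma_lkj * sigma_lkj.t()) % rho;
      Siginv = arma::inv_sympd(arma::symmatu(Sigma));
    }

    // --- record -----------------------------------------------------------
    if (t > n_burn) {
      int k = t - n_burn - 1;
      keep_mu.row(k) = mu.t();
      arma::vec sd = arma::sqrt(Sigma.diag());
      keep_sigma.row(k) = sd.t();
      keep_tau.row(k) = arma::sqrt(tau2).t();
      int p = 0;
      for (int a = 0; a < J - 1; ++a) {
        for (int b = a + 1; b < J; ++b) {
          keep_rho(k, p++) = Sigma(a, b) / (sd(a) * sd(b));
        }
      }
      theta_mean += theta;
      if (design == 2) alpha_mean += alpha;
      if (store_theta) theta_draws.slice(k) = theta;
    }
  }

  theta_mean /= n_keep;
  alpha_mean /= n_keep;

  List out = List::create(
    _["mu"] = keep_mu, _["sigma"] = keep_sigma, _["tau"] = keep_tau,
    _["rho"] = keep_rho, _["theta_mean"] = theta_mean,
    _["alpha_mean"] = alpha_mean,
    _["accept_rho"] = (prior_type == 2 && n_prop > 0) ? acc_rho / n_prop : NA_REAL,
    _["accept_sigma"] = (prior_type == 2 && n_prop > 0)
        ? NumericVector(wrap(acc_sig / n_prop)) : NumericVector(0),
    _["step_rho"] = step_rho, _["step_sigma"] = NumericVector(wrap(step_sig)));
  if (store_theta) out["theta"] = theta_draws;
  return out;
}
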