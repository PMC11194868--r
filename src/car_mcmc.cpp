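// MCMC engines for the spatial Poisson models.
//
// Both samplers are Metropolis-within-Gibbs with scalar random-walk updates,
// proposal scales auto-tuned during burn-in only (targets ~45% acceptance for
// scalar updates), and use R's RNG so that a set.seed() in the calling R
// session makes whole chains reproducible bit for bit.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clamp_sd(double s) {
  if (s < 1e-5) return 1e-5;
  if (s > 20.0) return 20.0;
  return s;
}

// adapt a proposal sd toward a target acceptance rate
static inline void adapt(double &sd, int &acc, int window, double target) {
  double rate = (double)acc / window;
  sd = clamp_sd(sd * std::exp(1.5 * (rate - target)));
  acc = 0;
}

// [[Rcpp::export(name = ".leroux_mcmc_cpp")]]
List leroux_mcmc_cpp(IntegerVector y, NumericVector logE, NumericMatrix X,
                     List nb, NumericVector evals,
                     int n_iter, int burn_in, int thin,
                     double beta_var, double ig_shape, double ig_scale,
                     double fix_rho, double fix_tau2,
                     bool use_lik, bool recenter,
                     NumericVector beta_init) {
  const int n = y.size(), p = X.ncol();
  std::vector< std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nb[i];
    adj[i].assign(v.begin(), v.end());      // 0-based
  }
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> phi(n, 0.0), xb(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
    xb[i] = s;
  }
  double tau2 = (fix_tau2 > 0) ? fix_tau2 : 0.1;
  double rho  = (fix_rho >= 0) ? fix_rho  : 0.5;

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix beta_draws(n_keep, p), phi_draws(n_keep, n), ll_draws(n_keep, n);
  NumericVector tau2_draws(n_keep), rho_draws(n_keep);

  std::vector<double> sd_beta(p, 0.05);
  double sd_phi = 0.1, sd_rho = 0.05;
  std::vector<int> acc_beta(p, 0);
  int acc_phi = 0, acc_rho = 0, try_phi = 0;
  long long tot_acc_beta = 0, tot_try_beta = 0, tot_acc_phi = 0, tot_try_phi = 0;
  long long tot_acc_rho = 0, tot_try_rho = 0;
  const int window = 100;

  int keep = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // --- beta: per-coefficient random walk ---
    for (int j = 0; j < p; ++j) {
      double db = sd_beta[j] * norm_rand();
      double bnew = beta[j] + db;
      double lr = (beta[j] * beta[j] - bnew * bnew) / (2.0 * beta_var);
      if (use_lik) {
        for (int i = 0; i < n; ++i) {
          double d = X(i, j) * db;
          if (d != 0.0) {
            double e_old = std::exp(logE[i] + xb[i] + phi[i]);
            lr += y[i] * d - e_old * (std::exp(d) - 1.0);
          }
        }
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        beta[j] = bnew;
        for (int i = 0; i < n; ++i) xb[i] += X(i, j) * db;
        acc_beta[j]++; tot_acc_beta++;
      }
      tot_try_beta++;
    }

    // --- phi: Metropolis within Gibbs, Leroux full-conditional prior ---
    for (int i = 0; i < n; ++i) {
      double di = (double)adj[i].size();
      double nbsum = 0.0;
      for (size_t k = 0; k < adj[i].size(); ++k) nbsum += phi[adj[i][k]];
      double prec = (rho * di + 1.0 - rho) / tau2;
      double m = rho * nbsum / (rho * di + 1.0 - rho);
      double pnew = phi[i] + sd_phi * norm_rand();
      double lr = -0.5 * prec * ((pnew - m) * (pnew - m) - (phi[i] - m) * (phi[i] - m));
      if (use_lik) {
        double e_base = std::exp(logE[i] + xb[i]);
        lr += y[i] * (pnew - phi[i]) - e_base * (std::exp(pnew) - std::exp(phi[i]));
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        phi[i] = pnew; acc_phi++; tot_acc_phi++;
      }
      try_phi++; tot_try_phi++;
    }

    // --- identifiability: recentre phi, absorb mean into the intercept ---
    if (recenter) {
      double mbar = 0.0;
      for (int i = 0; i < n; ++i) mbar += phi[i];
      mbar /= n;
      for (int i = 0; i < n; ++i) { phi[i] -= mbar; xb[i] += mbar; }
      beta[0] += mbar;
    }

    // quadratic forms for tau2 / rho
    double edge_ss = 0.0, phi_ss = 0.0;
    for (int i = 0; i < n; ++i) {
      phi_ss += phi[i] * phi[i];
      for (size_t k = 0; k < adj[i].size(); ++k) {
        int j = adj[i][k];
        if (j > i) { double d = phi[i] - phi[j]; edge_ss += d * d; }
      }
    }

    // --- tau2: conjugate inverse-gamma ---
    if (fix_tau2 <= 0) {
      double qf = rho * edge_ss + (1.0 - rho) * phi_ss;
      double shape = ig_shape + 0.5 * n;
      double rate = ig_scale + 0.5 * qf;
      tau2 = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    // --- rho: random walk on (0, 1) with exact log-determinant ---
    if (fix_rho < 0) {
      double rnew = rho + sd_rho * norm_rand();
      tot_try_rho++;
      if (rnew > 0.0 && rnew < 1.0 - 1e-8) {
        double lr = 0.0;
        for (int k = 0; k < n; ++k)
          lr += 0.5 * (std::log(rnew * evals[k] + 1.0 - rnew)
                     - std::log(rho  * evals[k] + 1.0 - rho));
        double qf_new = rnew * edge_ss + (1.0 - rnew) * phi_ss;
        double qf_old = rho  * edge_ss + (1.0 - rho)  * phi_ss;
        lr -= (qf_new - qf_old) / (2.0 * tau2);
        if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
          rho = rnew; acc_rho++; tot_acc_rho++;
        }
      }
    }

    // --- burn-in adaptation ---
    if (iter < burn_in && (iter + 1) % window == 0) {
      for (int j = 0; j < p; ++j) adapt(sd_beta[j], acc_beta[j], window, 0.45);
      double rate_phi = (double)acc_phi / try_phi;
      sd_phi = clamp_sd(sd_phi * std::exp(1.5 * (rate_phi - 0.45)));
      acc_phi = 0; try_phi = 0;
      if (fix_rho < 0) adapt(sd_rho, acc_rho, window, 0.45);
    }

    // --- retention ---
    if (iter >= burn_in && (iter - burn_in) % thin == 0 && keep < n_keep) {
      for (int j = 0; j < p; ++j) beta_draws(keep, j) = beta[j];
      for (int i = 0; i < n; ++i) {
        phi_draws(keep, i) = phi[i];
        double mu = std::exp(logE[i] + xb[i] + phi[i]);
        ll_draws(keep, i) = R::dpois(y[i], mu, 1);
      }
      tau2_draws[keep] = tau2;
      rho_draws[keep] = rho;
      keep++;
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["phi"] = phi_draws,
    _["tau2"] = tau2_draws, _["rho"] = rho_draws,
    _["loglik"] = ll_draws,
    _["accept"] = List::create(
      _["beta"] = (double)tot_acc_beta / std::max(1LL, tot_try_beta),
      _["phi"] = (double)tot_acc_phi / std::max(1LL, tot_try_phi),
      _["rho"] = fix_rho < 0 ? (double)tot_acc_rho / std::max(1LL, tot_try_rho)
                             : NA_REAL));
}

// [[Rcpp::export(name = ".localised_mcmc_cpp")]]
List localised_mcmc_cpp(IntegerVector y, NumericVector logE, NumericMatrix X,
                        int G, int n_iter, int burn_in, int thin,
                        double beta_var, double lambda_var,
                        double ig_shape, double ig_scale,
                        double delta_lo, double delta_hi,
                        bool use_lik,
                        NumericVector lambda_init, IntegerVector z_init,
                        NumericVector beta_init) {
  const int n = y.size(), p = X.ncol();
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<double> xb(n, 0.0), theta(n, 0.0), lambda(lambda_init.begin(), lambda_init.end());
  std::vector<int> z(z_init.begin(), z_init.end());  // 0-based classes
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += X(i, j) * beta[j];
    xb[i] = s;
  }
  double sigma2 = 0.1;
  // start at the weakest penalty so the likelihood, not the penalty,
  // decides the initial class occupancy
  double delta = delta_lo + 0.01 * (delta_hi - delta_lo);
  const double Gstar = (G + 1.0) / 2.0;   // centre class of the penalty

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix beta_draws(n_keep, std::max(p, 1)), theta_draws(n_keep, n),
                lambda_draws(n_keep, G), ll_draws(n_keep, n);
  IntegerMatrix z_draws(n_keep, n);
  NumericVector sigma2_draws(n_keep), delta_draws(n_keep);

  std::vector<double> sd_beta(p, 0.05);
  double sd_theta = 0.1, sd_lambda = 0.05, sd_delta = 0.5;
  std::vector<int> acc_beta(p, 0);
  int acc_theta = 0, try_theta = 0, acc_lambda = 0, try_lambda = 0, acc_delta = 0;
  long long tot_acc_theta = 0, tot_try_theta = 0, tot_acc_lambda = 0,
            tot_try_lambda = 0, tot_acc_delta = 0, tot_try_delta = 0,
            tot_acc_beta = 0, tot_try_beta = 0;
  const int window = 100;

  std::vector<double> logw(G);
  int keep = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // --- beta ---
    for (int j = 0; j < p; ++j) {
      double db = sd_beta[j] * norm_rand();
      double bnew = beta[j] + db;
      double lr = (beta[j] * beta[j] - bnew * bnew) / (2.0 * beta_var);
      if (use_lik) {
        for (int i = 0; i < n; ++i) {
          double d = X(i, j) * db;
          if (d != 0.0) {
            double e_old = std::exp(logE[i] + xb[i] + lambda[z[i]] + theta[i]);
            lr += y[i] * d - e_old * (std::exp(d) - 1.0);
          }
        }
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        beta[j] = bnew;
        for (int i = 0; i < n; ++i) xb[i] += X(i, j) * db;
        acc_beta[j]++; tot_acc_beta++;
      }
      tot_try_beta++;
    }

    // --- cluster intercepts lambda, order enforced by rejection ---
    for (int g = 0; g < G; ++g) {
      double lnew = lambda[g] + sd_lambda * norm_rand();
      try_lambda++; tot_try_lambda++;
      double lo = (g == 0) ? R_NegInf : lambda[g - 1];
      double hi = (g == G - 1) ? R_PosInf : lambda[g + 1];
      if (lnew <= lo || lnew >= hi) continue;   // ordering violated: reject
      double lr = (lambda[g] * lambda[g] - lnew * lnew) / (2.0 * lambda_var);
      if (use_lik) {
        for (int i = 0; i < n; ++i) {
          if (z[i] == g) {
            double e_base = std::exp(logE[i] + xb[i] + theta[i]);
            lr += y[i] * (lnew - lambda[g])
                - e_base * (std::exp(lnew) - std::exp(lambda[g]));
          }
        }
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        lambda[g] = lnew; acc_lambda++; tot_acc_lambda++;
      }
    }

    // --- class labels Z: discrete Gibbs under the penalty prior ---
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int g = 0; g < G; ++g) {
        double gpos = g + 1.0;
        double w = -delta * (gpos - Gstar) * (gpos - Gstar);
        if (use_lik) {
          double e_base = std::exp(logE[i] + xb[i] + theta[i]);
          w += y[i] * lambda[g] - e_base * std::exp(lambda[g]);
        }
        logw[g] = w;
        if (w > mx) mx = w;
      }
      double tot = 0.0;
      for (int g = 0; g < G; ++g) { logw[g] = std::exp(logw[g] - mx); tot += logw[g]; }
      double u = unif_rand() * tot, cum = 0.0;
      int znew = G - 1;
      for (int g = 0; g < G; ++g) { cum += logw[g]; if (u <= cum) { znew = g; break; } }
      z[i] = znew;
    }

    // --- penalty parameter delta on (delta_lo, delta_hi) ---
    {
      double dnew = delta + sd_delta * norm_rand();
      tot_try_delta++;
      if (dnew > delta_lo && dnew < delta_hi) {
        double S2 = 0.0;
        for (int i = 0; i < n; ++i) {
          double gpos = z[i] + 1.0;
          S2 += (gpos - Gstar) * (gpos - Gstar);
        }
        double norm_old = 0.0, norm_new = 0.0;
        for (int g = 0; g < G; ++g) {
          double q = (g + 1.0 - Gstar) * (g + 1.0 - Gstar);
          norm_old += std::exp(-delta * q);
          norm_new += std::exp(-dnew * q);
        }
        double lr = -(dnew - delta) * S2 - n * (std::log(norm_new) - std::log(norm_old));
        if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
          delta = dnew; acc_delta++; tot_acc_delta++;
        }
      }
    }

    // --- theta: iid N(0, sigma2) random effects ---
    for (int i = 0; i < n; ++i) {
      double tnew = theta[i] + sd_theta * norm_rand();
      double lr = (theta[i] * theta[i] - tnew * tnew) / (2.0 * sigma2);
      if (use_lik) {
        double e_base = std::exp(logE[i] + xb[i] + lambda[z[i]]);
        lr += y[i] * (tnew - theta[i]) - e_base * (std::exp(tnew) - std::exp(theta[i]));
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        theta[i] = tnew; acc_theta++; tot_acc_theta++;
      }
      try_theta++; tot_try_theta++;
    }

    // --- identifiability: recentre theta, absorb mean into all lambdas ---
    if (use_lik) {
      double mbar = 0.0;
      for (int i = 0; i < n; ++i) mbar += theta[i];
      mbar /= n;
      for (int i = 0; i < n; ++i) theta[i] -= mbar;
      for (int g = 0; g < G; ++g) lambda[g] += mbar;
    }

    // --- sigma2: conjugate inverse-gamma ---
    {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += theta[i] * theta[i];
      sigma2 = 1.0 / R::rgamma(ig_shape + 0.5 * n, 1.0 / (ig_scale + 0.5 * ss));
    }

    // --- burn-in adaptation ---
    if (iter < burn_in && (iter + 1) % window == 0) {
      for (int j = 0; j < p; ++j) adapt(sd_beta[j], acc_beta[j], window, 0.45);
      double r1 = (double)acc_theta / std::max(1, try_theta);
      sd_theta = clamp_sd(sd_theta * std::exp(1.5 * (r1 - 0.45)));
      acc_theta = 0; try_theta = 0;
      double r2 = (double)acc_lambda / std::max(1, try_lambda);
      sd_lambda = clamp_sd(sd_lambda * std::exp(1.5 * (r2 - 0.45)));
      acc_lambda = 0; try_lambda = 0;
      adapt(sd_delta, acc_delta, window, 0.45);
    }

    // --- retention ---
    if (iter >= burn_in && (iter - burn_in) % thin == 0 && keep < n_keep) {
      for (int j = 0; j < p; ++j) beta_draws(keep, j) = beta[j];
      for (int i = 0; i < n; ++i) {
        theta_draws(keep, i) = theta[i];
        z_draws(keep, i) = z[i] + 1;     // back to 1-based classes
        double mu = std::exp(logE[i] + xb[i] + lambda[z[i]] + theta[i]);
        ll_draws(keep, i) = R::dpois(y[i], mu, 1);
      }
      for (int g = 0; g < G; ++g) lambda_draws(keep, g) = lambda[g];
      sigma2_draws[keep] = sigma2;
      delta_draws[keep] = delta;
      keep++;
    }
  }

  return List::create(
    _["beta"] = beta_draws, _["theta"] = theta_draws,
    _["lambda"] = lambda_draws, _["Z"] = z_draws,
    _["sigma2"] = sigma2_draws, _["delta"] = delta_draws,
    _["loglik"] = ll_draws,
    _["accept"] = List::create(
      _["beta"] = p > 0 ? (double)tot_acc_beta / std::max(1LL, tot_try_beta) : NA_REAL,
      _["theta"] = (double)tot_acc_theta / std::max(1LL, tot_try_theta),
      _["lambda"] = (double)tot_acc_lambda / std::max(1LL, tot_try_lambda),
      _["delta"] = (double)tot_acc_delta / std::max(1LL, tot_try_delta)));
}
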