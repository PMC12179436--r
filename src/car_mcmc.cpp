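#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for areal regression with a Leroux
// conditional autoregressive random effect:
//   y_i ~ Poisson(exp(x_i'beta + offset_i + phi_i))   (family = 0)
//   y_i ~ Normal(x_i'beta + offset_i + phi_i, nu2)    (family = 1)
//   phi ~ N(0, tau2 * Q(rho)^{-1}),  Q(rho) = rho*(D - W) + (1 - rho)*I
// beta: block random-walk MH with a fixed proposal Cholesky, globally
// scaled and adapted during burn-in. phi_i: univariate MH (Poisson) or
// conjugate draw (Gaussian). tau2, nu2: conjugate inverse-gamma. rho:
// random-walk MH using the precision log-determinant from the
// eigenvalues of (D - W).

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".car_mcmc_chain")]]
List car_mcmc_chain(NumericVector y, NumericMatrix X, NumericVector offset,
                    int family, List nb, IntegerMatrix pairs,
                    NumericVector lambda, bool spatial,
                    int n_burnin, int n_keep, int thin,
                    NumericVector beta_init, NumericMatrix prop_chol,
                    double beta_prior_sd, double tau2_a, double tau2_b,
                    double nu2_a, double nu2_b, double rho_fixed) {
  const int n = y.size(), p = X.ncol();
  const int n_iter = n_burnin + n_keep * thin;
  const bool sample_rho = spatial && rho_fixed < 0;
  const double rho_max = 0.999;

  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; ++i) nbr[i] = as<std::vector<int>>(nb[i]);
  std::vector<double> deg(n);
  for (int i = 0; i < n; ++i) deg[i] = (double)nbr[i].size();

  NumericVector beta = clone(beta_init);
  std::vector<double> phi(n, 0.0), eta_fixed(n);
  double tau2 = 0.1, nu2 = 1.0;
  double rho = spatial ? (sample_rho ? 0.5 : rho_fixed) : 0.0;
  if (family == 1) { // init nu2 from raw variance
    double m = mean(y), s = 0;
    for (int i = 0; i < n; ++i) s += (y[i] - m) * (y[i] - m);
    nu2 = std::max(s / std::max(n - 1, 1), 1e-6);
  }

  auto update_eta_fixed = [&]() {
    for (int i = 0; i < n; ++i) {
      double e = offset[i];
      for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
      eta_fixed[i] = e;
    }
  };
  update_eta_fixed();

  auto loglik = [&](const std::vector<double>& etaf) {
    double ll = 0;
    if (family == 0) {
      for (int i = 0; i < n; ++i) {
        double e = etaf[i] + phi[i];
        ll += y[i] * e - std::exp(e);
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double r = y[i] - etaf[i] - phi[i];
        ll += -0.5 * r * r / nu2;
      }
    }
    return ll;
  };

  double beta_scale = 1.0, rho_scale = 0.05;
  std::vector<double> phi_scale(n, 0.5);
  int acc_beta = 0, try_beta = 0, acc_rho = 0, try_rho = 0;
  std::vector<int> acc_phi(n, 0);
  int adapt_window = 100, since_adapt = 0;

  NumericMatrix beta_out(n_keep, p);
  NumericVector rho_out(n_keep), tau2_out(n_keep), nu2_out(n_keep);
  std::vector<double> phi_mean(n, 0.0);
  int kept = 0;

  std::vector<double> etaf_prop(n);
  NumericVector beta_prop(p), z(p);

  for (int it = 0; it < n_iter; ++it) {
    // --- beta block MH ---
    for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
    for (int j = 0; j < p; ++j) {
      double d = 0;
      for (int k2 = 0; k2 <= j; ++k2) d += prop_chol(k2, j) * z[k2]; // upper-tri
      beta_prop[j] = beta[j] + beta_scale * d;
    }
    for (int i = 0; i < n; ++i) {
      double e = offset[i];
      for (int j = 0; j < p; ++j) e += X(i, j) * beta_prop[j];
      etaf_prop[i] = e;
    }
    double lp_cur = 0, lp_prop = 0;
    for (int j = 0; j < p; ++j) {
      lp_cur  += -0.5 * beta[j] * beta[j] / (beta_prior_sd * beta_prior_sd);
      lp_prop += -0.5 * beta_prop[j] * beta_prop[j] / (beta_prior_sd * beta_prior_sd);
    }
    double la = loglik(etaf_prop) + lp_prop - loglik(eta_fixed) - lp_cur;
    ++try_beta;
    if (std::log(R::unif_rand()) < la) {
      beta = clone(beta_prop);
      eta_fixed = etaf_prop;
      ++acc_beta;
    }

    if (spatial) {
      // --- phi updates ---
      for (int i = 0; i < n; ++i) {
        double prec_pr = (rho * deg[i] + 1.0 - rho) / tau2;
        double msum = 0;
        for (int jn : nbr[i]) msum += phi[jn];
        double m_pr = (rho * msum / tau2) / prec_pr;
        if (family == 0) {
          double cur = phi[i];
          double prop = cur + phi_scale[i] * R::norm_rand();
          double ll_cur = y[i] * cur - std::exp(eta_fixed[i] + cur)
            - 0.5 * prec_pr * (cur - m_pr) * (cur - m_pr);
          double ll_prop = y[i] * prop - std::exp(eta_fixed[i] + prop)
            - 0.5 * prec_pr * (prop - m_pr) * (prop - m_pr);
          if (std::log(R::unif_rand()) < ll_prop - ll_cur) {
            phi[i] = prop;
            ++acc_phi[i];
          }
        } else {
          double prec = prec_pr + 1.0 / nu2;
          double mu = (m_pr * prec_pr + (y[i] - eta_fixed[i]) / nu2) / prec;
          phi[i] = mu + R::norm_rand() / std::sqrt(prec);
        }
      }
      // --- tau2 conjugate ---
      double s_edge = 0, s_sq = 0;
      for (int k2 = 0; k2 < pairs.nrow(); ++k2) {
        double d = phi[pairs(k2, 0)] - phi[pairs(k2, 1)];
        s_edge += d * d;
      }
      for (int i = 0; i < n; ++i) s_sq += phi[i] * phi[i];
      double quad = rho * s_edge + (1.0 - rho) * s_sq;
      tau2 = rinvgamma(tau2_a + 0.5 * n, tau2_b + 0.5 * quad);
      // --- rho MH ---
      if (sample_rho) {
        double prop = rho + rho_scale * R::norm_rand();
        ++try_rho;
        if (prop > 0.0 && prop < rho_max) {
          double ld_cur = 0, ld_prop = 0;
          for (int i = 0; i < n; ++i) {
            ld_cur  += std::log(rho * lambda[i] + 1.0 - rho);
            ld_prop += std::log(prop * lambda[i] + 1.0 - prop);
          }
          double q_cur = rho * s_edge + (1.0 - rho) * s_sq;
          double q_prop = prop * s_edge + (1.0 - prop) * s_sq;
          double la2 = 0.5 * (ld_prop - ld_cur) - (q_prop - q_cur) / (2.0 * tau2);
          if (std::log(R::unif_rand()) < la2) {
            rho = prop;
            ++acc_rho;
          }
        }
      }
    }
    // --- nu2 conjugate (gaussian) ---
    if (family == 1) {
      double rss = 0;
      for (int i = 0; i < n; ++i) {
        double r = y[i] - eta_fixed[i] - phi[i];
        rss += r * r;
      }
      nu2 = rinvgamma(nu2_a + 0.5 * n, nu2_b + 0.5 * rss);
    }

    // --- adaptation during burn-in ---
    if (it < n_burnin && ++since_adapt == adapt_window) {
      double ar = (double)acc_beta / std::max(try_beta, 1);
      beta_scale *= std::exp(ar > 0.234 ? 0.2 : -0.2);
      acc_beta = 0; try_beta = 0;
      if (spatial && family == 0) {
        for (int i = 0; i < n; ++i) {
          double ai = (double)acc_phi[i] / adapt_window;
          phi_scale[i] *= std::exp(ai > 0.44 ? 0.2 : -0.2);
          acc_phi[i] = 0;
        }
      }
      if (sample_rho) {
        double arho = (double)acc_rho / std::max(try_rho, 1);
        rho_scale *= std::exp(arho > 0.44 ? 0.2 : -0.2);
        rho_scale = std::min(rho_scale, 0.5);
        acc_rho = 0; try_rho = 0;
      }
      since_adapt = 0;
    }

    // --- keep ---
    if (it >= n_burnin && (it - n_burnin) % thin == thin - 1) {
      for (int j = 0; j < p; ++j) beta_out(kept, j) = beta[j];
      rho_out[kept] = rho;
      tau2_out[kept] = tau2;
      nu2_out[kept] = nu2;
      for (int i = 0; i < n; ++i) phi_mean[i] += phi[i];
      ++kept;
    }
  }
  for (int i = 0; i < n; ++i) phi_mean[i] /= std::max(kept, 1);

  return List::create(
    _["beta"] = beta_out, _["rho"] = rho_out, _["tau2"] = tau2_out,
    _["nu2"] = nu2_out, _["phi_mean"] = NumericVector(phi_mean.begin(), phi_mean.end()),
    _["accept_beta"] = (double)acc_beta / std::max(try_beta, 1));
}
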