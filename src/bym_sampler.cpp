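// Metropolis-within-Gibbs sampler for the hierarchical count models:
//   Y_i ~ Poisson(lambda_i)  or  NegBin(mean lambda_i, size theta)
//   log lambda_i = log E_i + x_i' beta [+ u_i + v_i]
//   u ~ ICAR(tau_u) on the contiguity graph, v_i ~ N(0, 1/tau_v)
// Fixed effects move in one adaptive multivariate random-walk block
// (Haario-style covariance adaptation during burn-in, frozen afterwards);
// u and v are single-site random walks with per-site scales adapted in
// batches toward 0.44 acceptance; tau_u, tau_v are conjugate Gibbs draws;
// the NB size parameter moves on the log scale. Identifiability of the
// intrinsic CAR field against the intercept is handled by recentring u to
// mean zero every iteration and absorbing the shift into beta[0] (exact on
// a connected graph; disabled when islands are present).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double ll_one(double y, double eta, bool negbin, double theta) {
  // log-density terms depending on eta only (normalising pieces cancel in
  // eta-moves; theta-moves use ll_theta_sum below)
  double lam = std::exp(eta);
  if (!negbin) return y * eta - lam;
  return y * eta - (theta + y) * std::log(theta + lam);
}

static double ll_theta_sum(const arma::vec& Y, const arma::vec& eta, double theta) {
  // all theta-dependent terms of the NB log-likelihood
  double s = 0.0;
  const double lgth = lgamma(theta), thlogth = theta * std::log(theta);
  for (arma::uword i = 0; i < Y.n_elem; ++i) {
    double lam = std::exp(eta(i));
    s += lgamma(Y(i) + theta) - lgth + thlogth
         - (theta + Y(i)) * std::log(theta + lam);
  }
  return s;
}

static double ll_sum(const arma::vec& Y, const arma::vec& eta, bool negbin,
                     double theta) {
  double s = 0.0;
  for (arma::uword i = 0; i < Y.n_elem; ++i)
    s += ll_one(Y(i), eta(i), negbin, theta);
  return s;
}

// [[Rcpp::export]]
List bym_mcmc(const arma::vec& Y, const arma::vec& logE, const arma::mat& X,
              const arma::ivec& nb_idx, const arma::ivec& nb_ptr,
              const arma::vec& Nnb,
              bool spatial, bool negbin,
              int n_iter, int burnin, int thin,
              double prior_beta_var,
              double tau_shape, double tau_rate,
              double theta_shape, double theta_rate,
              int icar_rank, bool recenter,
              arma::vec beta_init, double theta_init) {
  const int n = Y.n_elem, p = X.n_cols;
  const int n_keep = (n_iter - burnin) / thin;

  arma::vec beta = beta_init;
  arma::vec u(n, arma::fill::zeros), v(n, arma::fill::zeros);
  double tau_u = 1.0, tau_v = 1.0, theta = theta_init;
  arma::vec eta = logE + X * beta;

  // storage
  arma::mat keep_beta(n_keep, p), keep_u, keep_v;
  arma::vec keep_tau_u(n_keep), keep_tau_v(n_keep), keep_theta(n_keep);
  if (spatial) { keep_u.set_size(n_keep, n); keep_v.set_size(n_keep, n); }

  // adaptive state
  arma::vec prop_sd_u(n, arma::fill::value(0.1));
  arma::vec prop_sd_v(n, arma::fill::value(0.1));
  arma::vec acc_u(n, arma::fill::zeros), acc_v(n, arma::fill::zeros);
  double prop_sd_theta = 0.3, acc_theta = 0.0;
  int batch = 0, batch_len = 50;

  arma::vec beta_mean = beta;
  arma::mat beta_cov(p, p, arma::fill::zeros);
  arma::mat prop_chol = arma::eye(p, p) * 0.01;
  double beta_count = 1.0;
  int acc_beta = 0;

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects block ---
    {
      arma::vec z(p);
      for (int j = 0; j < p; ++j) z(j) = R::norm_rand();
      arma::vec beta_star = beta + prop_chol.t() * z;
      arma::vec eta_star = eta + X * (beta_star - beta);
      double d = ll_sum(Y, eta_star, negbin, theta) - ll_sum(Y, eta, negbin, theta)
        - 0.5 / prior_beta_var * (arma::dot(beta_star, beta_star) - arma::dot(beta, beta));
      if (std::log(R::unif_rand()) < d) {
        beta = beta_star; eta = eta_star; ++acc_beta;
      }
      // running moments for the adaptive proposal
      beta_count += 1.0;
      arma::vec delta = beta - beta_mean;
      beta_mean += delta / beta_count;
      beta_cov += (delta * (beta - beta_mean).t() - beta_cov) / beta_count;
      if (it >= 100 && it < burnin && it % 25 == 0) {
        arma::mat S = beta_cov * (5.6644 / p)   // 2.38^2 / p
          + arma::eye(p, p) * 1e-8;
        arma::mat C;
        if (arma::chol(C, S)) prop_chol = C;
      }
    }

    if (spatial) {
      // --- structured field u, single-site ---
      for (int i = 0; i < n; ++i) {
        if (Nnb(i) == 0) continue;           // island: u_i pinned at 0
        double m = 0.0;
        for (int k = nb_ptr(i); k < nb_ptr(i + 1); ++k) m += u(nb_idx(k));
        m /= Nnb(i);
        double prec = tau_u * Nnb(i);
        double du = R::norm_rand() * prop_sd_u(i);
        double unew = u(i) + du;
        double d = ll_one(Y(i), eta(i) + du, negbin, theta)
                 - ll_one(Y(i), eta(i), negbin, theta)
                 - 0.5 * prec * ((unew - m) * (unew - m) - (u(i) - m) * (u(i) - m));
        if (std::log(R::unif_rand()) < d) {
          u(i) = unew; eta(i) += du; acc_u(i) += 1.0;
        }
      }
      // --- unstructured field v, single-site ---
      for (int i = 0; i < n; ++i) {
        double dv = R::norm_rand() * prop_sd_v(i);
        double vnew = v(i) + dv;
        double d = ll_one(Y(i), eta(i) + dv, negbin, theta)
                 - ll_one(Y(i), eta(i), negbin, theta)
                 - 0.5 * tau_v * (vnew * vnew - v(i) * v(i));
        if (std::log(R::unif_rand()) < d) {
          v(i) = vnew; eta(i) += dv; acc_v(i) += 1.0;
        }
      }

      // --- per-site field swap: u_i += t, v_i -= t keeps eta fixed; the
      // conditional of t under the two priors is Gaussian, giving an exact
      // Gibbs reallocation between the structured and unstructured
      // components (the u/v split otherwise equilibrates very slowly) ---
      for (int i = 0; i < n; ++i) {
        if (Nnb(i) == 0) continue;
        double m = 0.0;
        for (int k = nb_ptr(i); k < nb_ptr(i + 1); ++k) m += u(nb_idx(k));
        m /= Nnb(i);
        double pu = tau_u * Nnb(i);
        double P = pu + tau_v;
        double mt = (pu * (m - u(i)) + tau_v * v(i)) / P;
        double t = mt + R::norm_rand() / std::sqrt(P);
        u(i) += t;
        v(i) -= t;
      }

      // --- interweaving: shift beta_j along the likelihood-flat direction
      // (beta_j += delta, v_i -= delta x_ij keeps eta fixed); the
      // conditional of delta is Gaussian, so this is an exact Gibbs move
      // that breaks the confounding of the fixed effects with v ---
      for (int j = 0; j < p; ++j) {
        double sx2 = arma::dot(X.col(j), X.col(j));
        double sxv = arma::dot(X.col(j), v);
        double P = tau_v * sx2 + 1.0 / prior_beta_var;
        double m = (tau_v * sxv - beta(j) / prior_beta_var) / P;
        double delta = m + R::norm_rand() / std::sqrt(P);
        beta(j) += delta;
        v -= delta * X.col(j);
      }

      // --- interweaving against u: beta_j += delta, u -= delta x_j keeps
      // eta fixed; the ICAR prior gives delta a Gaussian conditional with
      // precision tau_u x' Q x. Covariate columns are centred, so the move
      // preserves mean(u); the intercept column is skipped (handled by the
      // recentring above). ---
      for (int j = 1; j < p; ++j) {
        arma::vec x = X.col(j);
        arma::vec Qx = Nnb % x;
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int k = nb_ptr(i); k < nb_ptr(i + 1); ++k) s += x(nb_idx(k));
          Qx(i) -= s;
        }
        double xQx = arma::dot(x, Qx);
        if (xQx <= 0) continue;
        double P = tau_u * xQx + 1.0 / prior_beta_var;
        double m = (tau_u * arma::dot(Qx, u) - beta(j) / prior_beta_var) / P;
        double delta = m + R::norm_rand() / std::sqrt(P);
        beta(j) += delta;
        u -= delta * x;
      }

      // --- sum-to-zero recentring of u, absorbed by the intercept (exact
      // identifiability fix on an island-free graph; eta unchanged) ---
      if (recenter) {
        double ubar = arma::mean(u);
        u -= ubar;
        beta(0) += ubar;
      }

      // --- precisions, conjugate ---
      double ss_u = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = nb_ptr(i); k < nb_ptr(i + 1); ++k) {
          double diff = u(i) - u(nb_idx(k));
          ss_u += diff * diff;
        }
      ss_u *= 0.5;                           // each edge visited twice
      tau_u = R::rgamma(tau_shape + 0.5 * icar_rank, 1.0 / (tau_rate + 0.5 * ss_u));
      tau_v = R::rgamma(tau_shape + 0.5 * n, 1.0 / (tau_rate + 0.5 * arma::dot(v, v)));
    }

    // --- NB size parameter, log-scale random walk ---
    if (negbin) {
      double lth = std::log(theta) + R::norm_rand() * prop_sd_theta;
      double theta_star = std::exp(lth);
      double d = ll_theta_sum(Y, eta, theta_star) - ll_theta_sum(Y, eta, theta)
        + theta_shape * (std::log(theta_star) - std::log(theta))
        - theta_rate * (theta_star - theta);
      if (std::log(R::unif_rand()) < d) { theta = theta_star; acc_theta += 1.0; }
    }

    // --- proposal adaptation in batches during burn-in ---
    if (it < burnin && (it + 1) % batch_len == 0) {
      ++batch;
      double step = std::min(0.05, 1.0 / std::sqrt((double)batch));
      for (int i = 0; i < n; ++i) {
        if (acc_u(i) / batch_len > 0.44) prop_sd_u(i) *= std::exp(step);
        else prop_sd_u(i) *= std::exp(-step);
        if (acc_v(i) / batch_len > 0.44) prop_sd_v(i) *= std::exp(step);
        else prop_sd_v(i) *= std::exp(-step);
      }
      if (acc_theta / batch_len > 0.44) prop_sd_theta *= std::exp(step);
      else prop_sd_theta *= std::exp(-step);
      acc_u.zeros(); acc_v.zeros(); acc_theta = 0.0;
    }

    // --- store ---
    if (it >= burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      keep_beta.row(kept) = beta.t();
      if (spatial) {
        keep_u.row(kept) = u.t();
        keep_v.row(kept) = v.t();
        keep_tau_u(kept) = tau_u;
        keep_tau_v(kept) = tau_v;
      }
      keep_theta(kept) = theta;
      ++kept;
    }
  }

  return List::create(
    _["beta"] = keep_beta,
    _["u"] = keep_u, _["v"] = keep_v,
    _["tau_u"] = keep_tau_u, _["tau_v"] = keep_tau_v,
    _["theta"] = keep_theta,
    _["accept_beta"] = (double)acc_beta / n_iter);
}
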