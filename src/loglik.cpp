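// Fused belief filter + logistic-normal response log-likelihood for one
// block. Mirrors the R reference path (run_filter + response_loglik)
// exactly; used as the hot path during model inversion, where the objective
// is evaluated tens of thousands of times per fit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec softmax_v(const vec& x) {
  vec y = exp(x - x.max());
  return y / accu(y);
}

static inline vec logistic_v(const vec& x) {
  return 1.0 / (1.0 + exp(-x));
}

// log of the Gaussian mass on the zero-sum plane
static inline double log_Z(const vec& m, const mat& P) {
  double aPa = accu(P);
  double am = accu(m);
  return -am * am / (2.0 * aPa) - 0.5 * std::log(2.0 * M_PI * aPa);
}

static inline double log_mvn3(const vec& x, const vec& m, const mat& P) {
  mat L = chol(P, "lower");
  vec z = solve(trimatl(L), x - m);
  double logdet = 2.0 * accu(log(L.diag()));
  return -0.5 * (3.0 * std::log(2.0 * M_PI) + logdet + dot(z, z));
}

// params layout (see .cpp_param_vector in R/inversion.R):
// 0 eps, 1 eps_nb, 2 alpha, 3 tau_e, 4 tau_f, 5 kappa_e, 6 kappa_f,
// 7 q_e, 8 q_f, 9 w_dist, 10 mu_e0, 11 mu_f0, 12 sigma_e0, 13 sigma_f0,
// 14 theta1, 15 theta2, 16 theta3, 17-19 mu_f0_1..3 (baseline location)
// flags layout: 0 bayesian, 1 reduced, 2 full_response, 3 baseline,
// 4 d_topdown, 5 structure_d

// [[Rcpp::export]]
double block_loglik_cpp(const arma::mat& e, const arma::mat& clr_r,
                        double const_term, const arma::vec& par,
                        const arma::ivec& flags) {
  const bool bayesian = flags[0], reduced = flags[1],
             full_response = flags[2], baseline = flags[3],
             d_topdown = flags[4];
  const double eps = par[0], eps_nb = par[1], alpha = par[2],
               tau_e = par[3], tau_f = par[4], kappa_e = par[5],
               kappa_f = par[6], q_e = par[7], q_f = par[8],
               w_dist = par[9], mu_e0 = par[10], mu_f0 = par[11],
               sigma_e0 = par[12], sigma_f0 = par[13], theta1 = par[14],
               theta2 = par[15], theta3 = par[16];
  const uword T = e.n_rows;
  const mat I3 = eye(3, 3);
  double ll = const_term;

  if (baseline) {
    vec m = {par[17], par[18], par[19]};
    mat P = (1.0 + theta3) * I3;
    double lz = log_Z(m, P);
    for (uword t = 0; t < T; ++t) {
      ll += -lz + log_mvn3(clr_r.row(t).t(), m, P);
    }
    return std::isfinite(ll) ? ll : -datum::inf;
  }

  const uword d = reduced ? 6 : 9;
  // connectivity
  mat W_lat_e = -2.0 * kappa_e * (ones(6, 6) - eye(6, 6));
  mat W_lat_f = -2.0 * kappa_f * (ones(3, 3) - eye(3, 3));
  mat W_dist_fe(6, 3, fill::zeros);
  mat W_dist_ef(3, 6, fill::zeros);
  if (!reduced) {
    for (uword i = 0; i < 6; ++i) {
      W_dist_fe(i, i / 2) = w_dist;
      W_dist_ef(i / 2, i) = w_dist;
    }
    if (flags[5] && !d_topdown) W_dist_fe.zeros();
  }

  vec mu(d);
  mu.head(6).fill(mu_e0);
  if (!reduced) mu.tail(3).fill(mu_f0);
  mat Sigma(d, d, fill::zeros), Q(d, d, fill::zeros);
  if (bayesian) {
    for (uword i = 0; i < 6; ++i) {
      Sigma(i, i) = sigma_e0;
      Q(i, i) = q_e;
    }
    if (!reduced) {
      for (uword i = 6; i < 9; ++i) {
        Sigma(i, i) = sigma_f0;
        Q(i, i) = q_f;
      }
    }
  }

  for (uword t = 0; t < T; ++t) {
    // deterministic propagation g(mu)
    vec g(d);
    vec phi_e = logistic_v(mu.head(6) - kappa_e);
    if (reduced) {
      g = tau_e * mu + kappa_e + W_lat_e * phi_e;
    } else {
      vec phi_f = logistic_v(mu.tail(3) - kappa_f);
      g.head(6) = tau_e * mu.head(6) + kappa_e + W_lat_e * phi_e +
                  W_dist_fe * phi_f;
      g.tail(3) = tau_f * mu.tail(3) + kappa_f + W_lat_f * phi_f +
                  W_dist_ef * phi_e;
    }
    vec ge = g.head(6);
    vec pi = softmax_v(ge);
    vec et = e.row(t).t();

    if (bayesian) {
      // Jacobian blocks with phi' = phi (1 - phi)
      vec dphi_e = phi_e % (1.0 - phi_e);
      mat J(d, d, fill::zeros);
      J.submat(0, 0, 5, 5) = tau_e * eye(6, 6) +
                             W_lat_e * diagmat(dphi_e);
      if (!reduced) {
        vec phi_f = logistic_v(mu.tail(3) - kappa_f);
        vec dphi_f = phi_f % (1.0 - phi_f);
        J.submat(0, 6, 5, 8) = W_dist_fe * diagmat(dphi_f);
        J.submat(6, 0, 8, 5) = W_dist_ef * diagmat(dphi_e);
        J.submat(6, 6, 8, 8) = tau_f * eye(3, 3) +
                               W_lat_f * diagmat(dphi_f);
      }
      mat Shat = J * Sigma * J.t() + Q;
      Shat = 0.5 * (Shat + Shat.t());
      vec loglik_e(6);
      for (uword k = 0; k < 6; ++k) {
        loglik_e[k] = (et[k] == 1.0) ? std::log1p(-eps) : std::log(eps);
      }
      vec rho = softmax_v(loglik_e + ge);
      // Sigma_t = (Shat^{-1} + Y)^{-1} = Shat (I + Y Shat)^{-1}; Y has only
      // an exemplar block Ye, so the 9x9 inverse reduces to a 6x6 solve:
      // with N = I6 + Ye S11, Sigma_t = [S11 N^{-1}, S12 - S11 N^{-1} Ye S12;
      //                                  sym,        S22 - S21 N^{-1} Ye S12]
      mat Ye = diagmat(pi) - pi * pi.t();
      mat S11 = Shat.submat(0, 0, 5, 5);
      mat N = eye(6, 6) + Ye * S11;
      mat Snew(d, d);
      bool ok = true;
      if (reduced) {
        mat T11;
        ok = solve(T11, N.t(), S11.t());
        if (!ok) return -datum::inf;
        Snew = T11.t();
      } else {
        mat S12 = Shat.submat(0, 6, 5, 8);
        mat S22 = Shat.submat(6, 6, 8, 8);
        mat R(6, 9);
        R.cols(0, 5) = S11.t();
        R.cols(6, 8) = S12;
        mat T;  // N^{-T} [S11^T, S12] => T.t() = [S11 N^{-1}; ...]
        ok = solve(T, N.t(), R);
        if (!ok) return -datum::inf;
        mat T11 = T.cols(0, 5).t();      // S11 N^{-1}
        mat T21 = T.cols(6, 8).t();      // S21 N^{-1}
        mat YeS12 = Ye * S12;
        Snew.submat(0, 0, 5, 5) = T11;
        Snew.submat(0, 6, 5, 8) = S12 - T11 * YeS12;
        Snew.submat(6, 0, 8, 5) = T21;
        Snew.submat(6, 6, 8, 8) = S22 - T21 * YeS12;
      }
      Snew = 0.5 * (Snew + Snew.t());
      if (!Snew.is_finite()) return -datum::inf;
      vec delta(d, fill::zeros);
      delta.head(6) = rho - pi;
      mu = g + Snew * delta;
      Sigma = Snew;
    } else {
      vec rho(6);
      for (uword k = 0; k < 6; ++k) {
        rho[k] = (et[k] == 1.0) ? 1.0 - eps_nb : eps_nb;
      }
      if (reduced) {
        mu = ge + alpha * (rho - pi);
      } else {
        mu.head(6) = ge + alpha * (rho - pi);
        mu.tail(3) = g.tail(3);
      }
    }

    // response density parameters
    vec m(3);
    if (reduced) {
      vec w = exp(mu - mu.max());
      vec p = {w[0] + w[1], w[2] + w[3], w[4] + w[5]};
      p /= accu(p);
      vec lp = log(p);
      m = theta1 * (lp - mean(lp));
    } else {
      m = theta1 * mu.tail(3);
    }
    mat P = theta2 * I3;
    if (full_response) P += theta3 * Sigma.submat(6, 6, 8, 8);
    if (!P.is_finite() || !m.is_finite()) return -datum::inf;
    mat Pchol;
    if (!chol(Pchol, P)) return -datum::inf;
    ll += -log_Z(m, P) + log_mvn3(clr_r.row(t).t(), m, P);
    if (!std::isfinite(ll)) return -datum::inf;
  }
  return ll;
}
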