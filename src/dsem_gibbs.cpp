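// Gibbs sampler for the two-level dynamic-factor (DSEM-CFA) model.
//
// Update blocks per sweep:
//   (1) per-person (phi_i, log sigma2_i): joint random-walk Metropolis
//       against the Kalman-marginalized within likelihood (states
//       integrated out) times the conditional random-effect prior;
//       per-person proposal scale adapted during burn-in only.
//   (2) per-person within latent states: forward filtering backward
//       sampling (stationary initialization).
//   (3) person-item means m_ik (= nu_k + lambda_b_k eta_b_i + eps_b_ik):
//       conjugate normal.
//   (4) per-person trait score eta_b_i: conjugate normal.
//   (5) measurement parameters (lambda_w, theta_w, nu, lambda_b, theta_b):
//       conjugate normal / inverse-gamma; anchor loadings pinned at 1.
//   (6) fixed effects xi = (gamma_phi, gamma_logvar, beta...): conjugate
//       multivariate normal (gamma_eta_b fixed at 0 for identification).
//   (7) random-effect covariance Sigma_b: conjugate inverse-Wishart.
//
// All randomness uses R's RNG so set.seed() gives bit-identical chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// marginal log-likelihood of person's centered within data via Kalman
// filter; y is the full data matrix, m holds person-item means.
static double kalman_loglik(const NumericMatrix& y, const NumericMatrix& m,
                            int i, int ps, int len,
                            const arma::vec& lw, const arma::vec& tw,
                            double phi, double s2) {
  const int K = y.ncol();
  double mf = 0.0, P = s2 / (1.0 - phi * phi), ll = 0.0;
  for (int t = 0; t < len; ++t) {
    if (t > 0) { mf = phi * mf; P = phi * phi * P + s2; }
    double a = 0.0, b = 0.0, q0 = 0.0, ld0 = 0.0;
    int nobs = 0;
    const int r = ps + t;
    for (int k = 0; k < K; ++k) {
      double yv = y(r, k);
      if (!ISNAN(yv)) {
        double res = yv - m(i, k) - lw[k] * mf;
        a += lw[k] * lw[k] / tw[k];
        b += lw[k] * res / tw[k];
        q0 += res * res / tw[k];
        ld0 += std::log(tw[k]);
        ++nobs;
      }
    }
    if (nobs > 0) {
      double denom = 1.0 + P * a;
      double quad = q0 - P * b * b / denom;
      ll += -0.5 * (nobs * M_LN_SQRT_2PI * 2.0 + ld0 + std::log(denom) + quad);
      double Pf = P / denom;
      mf = mf + Pf * b;
      P = Pf;
    }
  }
  return ll;
}

// forward filtering backward sampling of the within states for person i
static void ffbs_states(const NumericMatrix& y, const NumericMatrix& m,
                        int i, int ps, int len,
                        const arma::vec& lw, const arma::vec& tw,
                        double phi, double s2, NumericVector& states) {
  const int K = y.ncol();
  std::vector<double> mf(len), Pf(len);
  double mp = 0.0, P = s2 / (1.0 - phi * phi);
  for (int t = 0; t < len; ++t) {
    if (t > 0) { mp = phi * mf[t - 1]; P = phi * phi * Pf[t - 1] + s2; }
    double a = 0.0, b = 0.0;
    const int r = ps + t;
    for (int k = 0; k < K; ++k) {
      double yv = y(r, k);
      if (!ISNAN(yv)) {
        double res = yv - m(i, k) - lw[k] * mp;
        a += lw[k] * lw[k] / tw[k];
        b += lw[k] * res / tw[k];
      }
    }
    double denom = 1.0 + P * a;
    Pf[t] = P / denom;
    mf[t] = mp + Pf[t] * b;
  }
  // backward draws
  double prev = R::rnorm(mf[len - 1], std::sqrt(std::max(Pf[len - 1], 0.0)));
  states[ps + len - 1] = prev;
  for (int t = len - 2; t >= 0; --t) {
    double Ppred = phi * phi * Pf[t] + s2;
    double G = phi * Pf[t] / Ppred;
    double cm = mf[t] + G * (prev - phi * mf[t]);
    double cv = Pf[t] - G * phi * Pf[t];
    prev = R::rnorm(cm, std::sqrt(std::max(cv, 0.0)));
    states[ps + t] = prev;
  }
}

static arma::mat ranef_design_row(const arma::rowvec& x, int q) {
  const int p = x.n_elem;
  arma::mat A(3, q, arma::fill::zeros);
  A(1, 0) = 1.0;
  A(2, 1) = 1.0;
  for (int j = 0; j < p; ++j) {
    A(0, 2 + j) = x[j];
    A(1, 2 + p + j) = x[j];
    A(2, 2 + 2 * p + j) = x[j];
  }
  return A;
}

// inverse-Wishart draw via Bartlett decomposition using R's RNG
static arma::mat riwish(double df, const arma::mat& S) {
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  const int p = S.n_rows;
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::rnorm(0.0, 1.0);
  }
  arma::mat W = L * A * A.t() * L.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// [[Rcpp::export(name = ".dsem_gibbs")]]
List dsem_gibbs(NumericMatrix y, IntegerVector person_start,
                IntegerVector person_len, NumericMatrix X,
                int anchor, List priors, List init, List control, List fix) {
  const int K = y.ncol();
  const int n = person_start.size();
  const int p = X.ncol();
  const int q = 2 + 3 * p;

  const double li_mean = priors["li_mean"], li_var = priors["li_var"];
  const double fe_mean = priors["fe_mean"], fe_var = priors["fe_var"];
  const double ig_shape = priors["ig_shape"], ig_rate = priors["ig_rate"];
  const arma::mat iw_scale = as<arma::mat>(priors["iw_scale"]);
  const double iw_df = priors["iw_df"];

  const int n_iter = control["n_iter"];
  const int thin = control["thin"];
  const bool adapt = control["adapt"];
  const int burn_in = control["burn_in"];
  const bool store_ranef = control["store_ranef"];

  const bool fix_lambda_w = fix["lambda_w"], fix_theta_w = fix["theta_w"];
  const bool fix_nu_lambda_b = fix["nu_lambda_b"], fix_theta_b = fix["theta_b"];
  const bool fix_eta_b = fix["eta_b"], fix_phi_v = fix["phi_v"];
  const bool fix_m = fix["m"], fix_states = fix["states"];
  const bool fix_xi = fix["xi"], fix_sigma_b = fix["sigma_b"];

  arma::vec nu = as<arma::vec>(init["nu"]);
  arma::vec lw = as<arma::vec>(init["lw"]);
  arma::vec lb = as<arma::vec>(init["lb"]);
  arma::vec tw = as<arma::vec>(init["tw"]);
  arma::vec tb = as<arma::vec>(init["tb"]);
  arma::mat u = as<arma::mat>(init["u"]);        // n x 3 (eta_b, phi, v)
  NumericMatrix m = clone(as<NumericMatrix>(init["m"]));   // n x K
  arma::vec xi = as<arma::vec>(init["xi"]);      // q
  arma::mat Sigma = as<arma::mat>(init["Sigma"]);
  NumericVector states = clone(as<NumericVector>(init["states"]));
  arma::vec mh_scale = as<arma::vec>(init["mh_scale"]);

  arma::mat Adsn(3, q);
  arma::mat mu_re(n, 3);   // per-person random-effect means
  const arma::mat Xa = as<arma::mat>(wrap(X));

  const int npar = 5 * K + q + 6 + 2 * K + 3 + 1;
  const int n_stored = n_iter / thin;
  NumericMatrix draws(n_stored, npar);
  NumericVector ranef_draws;
  if (store_ranef) {
    ranef_draws = NumericVector(Dimension(n_stored, n, 3));
  }
  arma::vec n_accept(n, arma::fill::zeros);
  long phi_rejects = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // per-person random-effect means mu_i = A_i xi
    for (int i = 0; i < n; ++i) {
      mu_re(i, 0) = 0.0; mu_re(i, 1) = xi[0]; mu_re(i, 2) = xi[1];
      for (int j = 0; j < p; ++j) {
        mu_re(i, 0) += Xa(i, j) * xi[2 + j];
        mu_re(i, 1) += Xa(i, j) * xi[2 + p + j];
        mu_re(i, 2) += Xa(i, j) * xi[2 + 2 * p + j];
      }
    }

    // conditional prior of (phi, v) | eta_b  (shared across persons)
    const double s11 = Sigma(0, 0);
    arma::vec s21 = { Sigma(1, 0), Sigma(2, 0) };
    arma::mat S22 = { { Sigma(1, 1), Sigma(1, 2) },
                      { Sigma(2, 1), Sigma(2, 2) } };
    arma::mat condCov = S22 - s21 * s21.t() / s11;
    arma::mat condPrec = arma::inv_sympd(arma::symmatu(condCov));

    // ---- (1) Metropolis update of (phi_i, v_i) ----
    if (!fix_phi_v) {
      for (int i = 0; i < n; ++i) {
        const int ps = person_start[i], len = person_len[i];
        double phi = u(i, 1), v = u(i, 2);
        double cm1 = mu_re(i, 1) + s21[0] / s11 * (u(i, 0) - mu_re(i, 0));
        double cm2 = mu_re(i, 2) + s21[1] / s11 * (u(i, 0) - mu_re(i, 0));
        auto lprior = [&](double a, double b) {
          double d1 = a - cm1, d2 = b - cm2;
          return -0.5 * (condPrec(0, 0) * d1 * d1 +
                         2.0 * condPrec(0, 1) * d1 * d2 +
                         condPrec(1, 1) * d2 * d2);
        };
        double cur = kalman_loglik(y, m, i, ps, len, lw, tw, phi, std::exp(v)) +
          lprior(phi, v);
        double phi_p = phi + 0.15 * mh_scale[i] * R::rnorm(0.0, 1.0);
        double v_p = v + 0.50 * mh_scale[i] * R::rnorm(0.0, 1.0);
        bool acc = false;
        if (std::fabs(phi_p) >= 0.999) {
          ++phi_rejects;
        } else {
          double prop = kalman_loglik(y, m, i, ps, len, lw, tw, phi_p,
                                      std::exp(v_p)) + lprior(phi_p, v_p);
          if (std::log(R::runif(0.0, 1.0)) < prop - cur) {
            u(i, 1) = phi_p; u(i, 2) = v_p; acc = true;
          }
        }
        if (acc) n_accept[i] += 1.0;
        if (adapt && iter < burn_in) {
          double rate = 0.5 / std::sqrt(1.0 + iter);
          mh_scale[i] = std::min(50.0, std::max(0.01,
            mh_scale[i] * std::exp(rate * ((acc ? 1.0 : 0.0) - 0.35))));
        }
      }
    }

    // ---- (2) FFBS latent states ----
    if (!fix_states) {
      for (int i = 0; i < n; ++i) {
        ffbs_states(y, m, i, person_start[i], person_len[i], lw, tw,
                    u(i, 1), std::exp(u(i, 2)), states);
      }
    }

    // ---- (3) person-item means m_ik ----
    if (!fix_m) {
      for (int i = 0; i < n; ++i) {
        const int ps = person_start[i], len = person_len[i];
        for (int k = 0; k < K; ++k) {
          double sz = 0.0; int cnt = 0;
          for (int t = 0; t < len; ++t) {
            double yv = y(ps + t, k);
            if (!ISNAN(yv)) { sz += yv - lw[k] * states[ps + t]; ++cnt; }
          }
          double prior_mean = nu[k] + lb[k] * u(i, 0);
          double prec = 1.0 / tb[k] + cnt / tw[k];
          double mean = (prior_mean / tb[k] + sz / tw[k]) / prec;
          m(i, k) = R::rnorm(mean, std::sqrt(1.0 / prec));
        }
      }
    }

    // ---- (3b) level interweaving ----
    // Exact Gibbs draw along the near-ridge direction that trades the
    // person-item means against the latent-state level:
    //   m_ik <- m_ik + lambda_w_k * c_i,   a_it <- a_it - c_i.
    // The within likelihood is invariant along this direction, so c_i has
    // a closed-form normal conditional from the m-prior and the AR prior
    // of the shifted states. Without this move the m/state split mixes
    // extremely slowly for short series with high carryover.
    if (!fix_m && !fix_states) {
      for (int i = 0; i < n; ++i) {
        const int ps = person_start[i], len = person_len[i];
        const double phi = u(i, 1), s2 = std::exp(u(i, 2));
        double prec = 0.0, lin = 0.0;
        for (int k = 0; k < K; ++k) {
          double d = m(i, k) - nu[k] - lb[k] * u(i, 0);
          prec += lw[k] * lw[k] / tb[k];
          lin += -lw[k] * d / tb[k];
        }
        const double a1 = states[ps];
        prec += (1.0 - phi * phi) / s2;
        lin += (1.0 - phi * phi) * a1 / s2;
        double esum = 0.0;
        for (int t = 1; t < len; ++t) {
          esum += states[ps + t] - phi * states[ps + t - 1];
        }
        prec += (len - 1) * (1.0 - phi) * (1.0 - phi) / s2;
        lin += (1.0 - phi) * esum / s2;
        const double c = R::rnorm(lin / prec, std::sqrt(1.0 / prec));
        for (int k = 0; k < K; ++k) m(i, k) += lw[k] * c;
        for (int t = 0; t < len; ++t) states[ps + t] -= c;
      }
    }

    // ---- (4) trait scores eta_b_i ----
    if (!fix_eta_b) {
      arma::mat S23 = { { Sigma(0, 1), Sigma(0, 2) } };  // 1 x 2
      arma::mat S22i = arma::inv_sympd(arma::symmatu(S22));
      arma::rowvec w = (S23 * S22i);
      double condv = s11 - arma::as_scalar(S23 * S22i * S23.t());
      double lik_prec = 0.0;
      for (int k = 0; k < K; ++k) lik_prec += lb[k] * lb[k] / tb[k];
      for (int i = 0; i < n; ++i) {
        double pm = mu_re(i, 0) + w[0] * (u(i, 1) - mu_re(i, 1)) +
          w[1] * (u(i, 2) - mu_re(i, 2));
        double lik_mean_num = 0.0;
        for (int k = 0; k < K; ++k) {
          lik_mean_num += lb[k] * (m(i, k) - nu[k]) / tb[k];
        }
        double prec = 1.0 / condv + lik_prec;
        double mean = (pm / condv + lik_mean_num) / prec;
        u(i, 0) = R::rnorm(mean, std::sqrt(1.0 / prec));
      }
    }

    // ---- (5) measurement parameters ----
    if (!fix_lambda_w || !fix_theta_w) {
      for (int k = 0; k < K; ++k) {
        double saa = 0.0, saz = 0.0;
        int cnt = 0;
        for (int i = 0; i < n; ++i) {
          const int ps = person_start[i], len = person_len[i];
          for (int t = 0; t < len; ++t) {
            double yv = y(ps + t, k);
            if (!ISNAN(yv)) {
              double z = yv - m(i, k);
              double a = states[ps + t];
              saa += a * a; saz += a * z; ++cnt;
            }
          }
        }
        if (!fix_lambda_w && k != anchor) {
          double prec = 1.0 / li_var + saa / tw[k];
          double mean = (li_mean / li_var + saz / tw[k]) / prec;
          lw[k] = R::rnorm(mean, std::sqrt(1.0 / prec));
        }
        if (!fix_theta_w) {
          double sse = 0.0;
          for (int i = 0; i < n; ++i) {
            const int ps = person_start[i], len = person_len[i];
            for (int t = 0; t < len; ++t) {
              double yv = y(ps + t, k);
              if (!ISNAN(yv)) {
                double e = yv - m(i, k) - lw[k] * states[ps + t];
                sse += e * e;
              }
            }
          }
          tw[k] = std::max(1e-10,
            1.0 / R::rgamma(ig_shape + 0.5 * cnt, 1.0 / (ig_rate + 0.5 * sse)));
        }
      }
    }

    if (!fix_nu_lambda_b || !fix_theta_b) {
      for (int k = 0; k < K; ++k) {
        if (!fix_nu_lambda_b) {
          if (k == anchor) {
            // lambda_b fixed at 1: intercept-only regression on m - eta_b
            double s = 0.0;
            for (int i = 0; i < n; ++i) s += m(i, k) - u(i, 0);
            double prec = 1.0 / li_var + n / tb[k];
            double mean = (li_mean / li_var + s / tb[k]) / prec;
            nu[k] = R::rnorm(mean, std::sqrt(1.0 / prec));
          } else {
            double se = 0.0, see = 0.0, sm = 0.0, sem = 0.0;
            for (int i = 0; i < n; ++i) {
              se += u(i, 0); see += u(i, 0) * u(i, 0);
              sm += m(i, k); sem += u(i, 0) * m(i, k);
            }
            arma::mat P = { { n / tb[k] + 1.0 / li_var, se / tb[k] },
                            { se / tb[k], see / tb[k] + 1.0 / li_var } };
            arma::vec bv = { sm / tb[k] + li_mean / li_var,
                             sem / tb[k] + li_mean / li_var };
            arma::mat Pc = arma::chol(P);
            arma::vec mean = arma::solve(arma::trimatu(Pc),
                              arma::solve(arma::trimatl(Pc.t()), bv));
            arma::vec zr = { R::rnorm(0.0, 1.0), R::rnorm(0.0, 1.0) };
            arma::vec draw = mean + arma::solve(arma::trimatu(Pc), zr);
            nu[k] = draw[0]; lb[k] = draw[1];
          }
        }
        if (!fix_theta_b) {
          double sse = 0.0;
          for (int i = 0; i < n; ++i) {
            double e = m(i, k) - nu[k] - lb[k] * u(i, 0);
            sse += e * e;
          }
          tb[k] = std::max(1e-10,
            1.0 / R::rgamma(ig_shape + 0.5 * n, 1.0 / (ig_rate + 0.5 * sse)));
        }
      }
    }

    // ---- (6) fixed effects xi ----
    arma::mat W = arma::inv_sympd(arma::symmatu(Sigma));
    if (!fix_xi) {
      arma::mat Prec(q, q, arma::fill::zeros);
      Prec.diag().fill(1.0 / fe_var);
      arma::vec bv(q, arma::fill::value(fe_mean / fe_var));
      for (int i = 0; i < n; ++i) {
        arma::rowvec xr(p);
        if (p > 0) xr = Xa.row(i);
        Adsn = ranef_design_row(xr, q);
        Prec += Adsn.t() * W * Adsn;
        bv += Adsn.t() * W * u.row(i).t();
      }
      arma::mat Pc = arma::chol(Prec);
      arma::vec mean = arma::solve(arma::trimatu(Pc),
                        arma::solve(arma::trimatl(Pc.t()), bv));
      arma::vec zr(q);
      for (int j = 0; j < q; ++j) zr[j] = R::rnorm(0.0, 1.0);
      xi = mean + arma::solve(arma::trimatu(Pc), zr);
    }

    // ---- (7) random-effect covariance Sigma_b ----
    if (!fix_sigma_b) {
      arma::mat S = iw_scale;
      for (int i = 0; i < n; ++i) {
        arma::rowvec xr(p);
        if (p > 0) xr = Xa.row(i);
        Adsn = ranef_design_row(xr, q);
        arma::vec e = u.row(i).t() - Adsn * xi;
        S += e * e.t();
      }
      Sigma = riwish(iw_df + n, S);
    }

    // ---- store ----
    if ((iter + 1) % thin == 0) {
      const int row = (iter + 1) / thin - 1;
      int c = 0;
      for (int k = 0; k < K; ++k) draws(row, c++) = nu[k];
      for (int k = 0; k < K; ++k) draws(row, c++) = lw[k];
      for (int k = 0; k < K; ++k) draws(row, c++) = lb[k];
      for (int k = 0; k < K; ++k) draws(row, c++) = tw[k];
      for (int k = 0; k < K; ++k) draws(row, c++) = tb[k];
      for (int j = 0; j < q; ++j) draws(row, c++) = xi[j];
      draws(row, c++) = Sigma(0, 0);
      draws(row, c++) = Sigma(1, 0);
      draws(row, c++) = Sigma(1, 1);
      draws(row, c++) = Sigma(2, 0);
      draws(row, c++) = Sigma(2, 1);
      draws(row, c++) = Sigma(2, 2);
      for (int k = 0; k < K; ++k) draws(row, c++) = lb[k] - lw[k];
      for (int k = 0; k < K; ++k) draws(row, c++) = lb[k] / lw[k];
      draws(row, c++) = Sigma(1, 2) / std::sqrt(Sigma(1, 1) * Sigma(2, 2));
      draws(row, c++) = Sigma(0, 1) / std::sqrt(Sigma(0, 0) * Sigma(1, 1));
      draws(row, c++) = Sigma(0, 2) / std::sqrt(Sigma(0, 0) * Sigma(2, 2));
      double vbar = 0.0;
      for (int i = 0; i < n; ++i) {
        vbar += std::exp(u(i, 2)) / (1.0 - u(i, 1) * u(i, 1));
      }
      draws(row, c++) = vbar / n;
      if (store_ranef) {
        for (int i = 0; i < n; ++i) {
          for (int j = 0; j < 3; ++j) {
            ranef_draws[row + n_stored * (i + n * j)] = u(i, j);
          }
        }
      }
    }
  }

  List out = List::create(
    Named("draws") = draws,
    Named("accept_rate") = wrap(arma::vec(n_accept / double(n_iter))),
    Named("phi_rejections") = (double)phi_rejects,
    Named("mh_scale") = wrap(mh_scale),
    Named("final_state") = List::create(
      Named("nu") = wrap(nu), Named("lw") = wrap(lw), Named("lb") = wrap(lb),
      Named("tw") = wrap(tw), Named("tb") = wrap(tb), Named("u") = wrap(u),
      Named("m") = m, Named("xi") = wrap(xi), Named("Sigma") = wrap(Sigma),
      Named("states") = states, Named("mh_scale") = wrap(mh_scale)));
  if (store_ranef) out["ranef_draws"] = ranef_draws;
  return out;
}
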