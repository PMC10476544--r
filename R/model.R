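#' Model specification for a one-factor two-level dynamic CFA
#'
#' @param item_ids character vector of item column names (K >= 2; 7 for a
#'   DASS-21 subscale).
#' @param anchor_item item whose unstandardized loading is fixed to 1 at
#'   both levels; it sets the common scale needed for cross-level loading
#'   comparisons and must itself be cross-level invariant (see
#'   [select_anchor()]).
#' @param covariate_ids person-level covariate columns to include at the
#'   between level (empty for the unconditional model).
#' @param priors a [default_priors()] list.
#' @return Object of class `dsem_model_spec`.
#' @export
dsem_model_spec <- function(item_ids, anchor_item = item_ids[1],
                            covariate_ids = character(),
                            priors = default_priors()) {
  stopifnot(length(item_ids) >= 1L)
  if (!anchor_item %in% item_ids) {
    stop("model spec error: anchor_item must be one of item_ids", call. = FALSE)
  }
  structure(list(item_ids = item_ids, anchor_item = anchor_item,
                 covariate_ids = covariate_ids, priors = priors),
            class = "dsem_model_spec")
}

#' Proper diffuse default priors
#'
#' Diffuse but proper priors so the posterior is always well defined:
#' normal(0, 1e6) on loadings, item intercepts and fixed effects;
#' inverse-gamma(0.001, 0.001) on residual variances; inverse-Wishart with
#' identity scale and 5 degrees of freedom (dimension + 2, so the prior mean
#' of the random-effect covariance equals the scale matrix) on the 3x3
#' random-effect covariance.
#'
#' @return list with elements `loading_intercept_prior`,
#'   `fixed_effect_prior` (each `c(mean, var)`), `resid_var_prior`
#'   (`c(shape, rate)`), `ranef_cov_prior` (`list(scale, df)`).
#' @export
default_priors <- function() {
  list(loading_intercept_prior = c(mean = 0, var = 1e6),
       fixed_effect_prior = c(mean = 0, var = 1e6),
       resid_var_prior = c(shape = 0.001, rate = 0.001),
       ranef_cov_prior = list(scale = diag(3), df = 5))
}

#' Marginal log-likelihood of one person's within-level data
#'
#' Sequential linear-Gaussian (Kalman) filter for the state-space form of
#' the within model: latent state `eta_w[t] = phi * eta_w[t-1] + zeta[t]`
#' with stationary initialization `N(0, sigma2 / (1 - phi^2))`, observation
#' `y[t,k] = lambda_w[k] * eta_w[t] + e`, `e ~ N(0, theta_w[k])`. The latent
#' states are marginalized analytically; missing cells are skipped in the
#' observation update (an all-missing occasion contributes only a state
#' propagation step).
#'
#' `y` must already be centered at the person's between-level item means
#' (use [center_within()] for the centering implied by given random effects).
#'
#' @param y T x K matrix of centered within-level observations (NA allowed).
#' @param lambda_w within-level loadings (length K).
#' @param theta_w within-level residual variances (length K, positive).
#' @param phi carryover, `|phi| < 1`.
#' @param innovation_var innovation variance `sigma2_zeta > 0`.
#' @return log density (natural log).
#' @export
within_marginal_loglik <- function(y, lambda_w, theta_w, phi, innovation_var) {
  y <- as.matrix(y)
  if (abs(phi) >= 1) {
    stop("nonstationarity error: |phi| >= 1 has no stationary initial variance",
         call. = FALSE)
  }
  stopifnot(ncol(y) == length(lambda_w), length(theta_w) == length(lambda_w),
            all(theta_w > 0), innovation_var > 0)
  m <- 0
  P <- innovation_var / (1 - phi^2)
  ll <- 0
  for (t in seq_len(nrow(y))) {
    if (t > 1L) {
      m <- phi * m
      P <- phi^2 * P + innovation_var
    }
    obs <- which(!is.na(y[t, ]))
    if (length(obs) > 0L) {
      lam <- lambda_w[obs]
      th <- theta_w[obs]
      r <- y[t, obs] - lam * m
      # innovation covariance P * lam lam' + diag(th):
      # Sherman-Morrison / matrix determinant lemma keep this O(K)
      a <- sum(lam^2 / th)
      b <- sum(lam * r / th)
      denom <- 1 + P * a
      quad <- sum(r^2 / th) - P * b^2 / denom
      logdet <- sum(log(th)) + log(denom)
      ll <- ll - 0.5 * (length(obs) * log(2 * pi) + logdet + quad)
      # posterior (filtered) state
      Pf <- P / denom
      m <- m + Pf * b
      P <- Pf
    }
  }
  ll
}

#' Center a person's raw responses at their model-implied item means
#'
#' Subtracts `nu_k + lambda_b_k * eta_b + eps_b_k` from each item column.
#'
#' @param y T x K matrix of raw responses.
#' @param params list with `intercepts` and `loadings_between`.
#' @param eta_b the person's trait factor score.
#' @param eps_b optional person-item between residuals (default 0).
#' @return centered T x K matrix.
#' @export
center_within <- function(y, params, eta_b, eps_b = 0) {
  mean_k <- params$intercepts + params$loadings_between * eta_b + eps_b
  sweep(as.matrix(y), 2L, mean_k, "-")
}

# marginal log density of one person's raw data given (eta_b, phi, sigma2),
# with BOTH the within states and the between item residuals integrated out:
# cov(y[t,k], y[s,l]) = lw_k lw_l Gamma(|t-s|) + [k==l] theta_b_k
#                       + [t==s][k==l] theta_w_k
# Dense construction; used by joint_logposterior (not a sampler hot path).
person_marginal_loglik <- function(y, params, eta_b, phi, innovation_var) {
  y <- as.matrix(y)
  if (abs(phi) >= 1) {
    stop("nonstationarity error: |phi| >= 1", call. = FALSE)
  }
  K <- ncol(y); Tn <- nrow(y)
  lw <- params$loadings_within
  mu <- params$intercepts + params$loadings_between * eta_b
  resid <- sweep(y, 2L, mu, "-")
  obs <- which(!is.na(t(resid)))  # index in (t,k) stacked item-fastest
  r <- as.vector(t(resid))[obs]
  tt <- rep(seq_len(Tn), each = K)[obs]
  kk <- rep(seq_len(K), times = Tn)[obs]
  g0 <- innovation_var / (1 - phi^2)
  Gam <- g0 * phi^abs(outer(tt, tt, "-"))
  V <- outer(lw[kk], lw[kk]) * Gam +
    outer(kk, kk, "==") * params$resid_var_between[kk] +
    (outer(tt, tt, "==") & outer(kk, kk, "==")) * params$resid_var_within[kk]
  ch <- chol(V)
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (length(r) * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# multivariate normal log density (mean mu, covariance S)
dmvnorm_log <- function(x, mu, S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# log inverse-gamma density (shape a, rate b)
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

# log inverse-Wishart density, scale Psi, df nu, dimension p
dinvwishart_log <- function(S, Psi, df) {
  p <- nrow(S)
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) return(-Inf)
  lgammap <- (p * (p - 1) / 4) * log(pi) +
    sum(lgamma((df + 1 - seq_len(p)) / 2))
  ldetPsi <- as.numeric(determinant(Psi, logarithm = TRUE)$modulus)
  ldetS <- 2 * sum(log(diag(chS)))
  tr <- sum(diag(solve(S, Psi)))
  (df / 2) * ldetPsi - (df * p / 2) * log(2) - lgammap -
    ((df + p + 1) / 2) * ldetS - 0.5 * tr
}

# design rows mapping the fixed-effect vector xi to the per-person mean of
# (eta_b, phi, logvar). xi = (gamma_phi, gamma_logvar, beta_eta[1..p],
# beta_phi[1..p], beta_logvar[1..p]); gamma_eta_b is fixed to 0 for
# identification against the free item intercepts.
ranef_design <- function(x) {
  p <- length(x)
  A <- matrix(0, 3, 2 + 3 * p)
  A[2, 1] <- 1
  A[3, 2] <- 1
  if (p > 0) {
    A[1, 2 + seq_len(p)] <- x
    A[2, 2 + p + seq_len(p)] <- x
    A[3, 2 + 2 * p + seq_len(p)] <- x
  }
  A
}

params_to_xi <- function(params, covariate_ids) {
  p <- length(covariate_ids)
  xi <- c(params$gamma[2], params$gamma[3])
  if (p > 0) {
    B <- sapply(covariate_ids, function(cv) params$beta[[cv]])  # 3 x p
    xi <- c(xi, B[1, ], B[2, ], B[3, ])
  }
  unname(xi)
}

#' Joint log-posterior of parameters and person random effects
#'
#' Sums, over persons, the marginal log density of the person's data given
#' their random-effect triple (within latent states and between item
#' residuals integrated out analytically), the random-effect multivariate
#' normal density (mean shifted by covariate effects when present), and the
#' prior log densities. Returns `-Inf` (a rejected state, not an error) when
#' the random-effect covariance is not positive-definite.
#'
#' @param params parameter list with the [dsem_true_params()] fields
#'   (`loadings_*`, `intercepts`, `resid_var_*`, `gamma`, `Sigma_b`, `beta`).
#' @param ranefs data.frame with columns `person_id`, `eta_b`, `phi`,
#'   `log_innovation_var` (one row per person, panel order).
#' @param panel a `dsem_panel`.
#' @param spec a [dsem_model_spec()].
#' @return log posterior density (natural log), up to the normalizing
#'   constant of the data.
#' @export
joint_logposterior <- function(params, ranefs, panel, spec) {
  pri <- spec$priors
  ev <- eigen(params$Sigma_b, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)

  persons <- panel_person_split(panel)
  stopifnot(nrow(ranefs) == length(persons))
  ll <- 0
  for (i in seq_along(persons)) {
    per <- persons[[i]]
    re <- ranefs[i, ]
    ll <- ll + person_marginal_loglik(per$y, params, re$eta_b, re$phi,
                                      exp(re$log_innovation_var))
    A <- ranef_design(per$x[spec$covariate_ids])
    mu_i <- as.vector(A %*% params_to_xi(params, spec$covariate_ids))
    ll <- ll + dmvnorm_log(c(re$eta_b, re$phi, re$log_innovation_var),
                           mu_i, params$Sigma_b)
  }

  li <- pri$loading_intercept_prior
  fe <- pri$fixed_effect_prior
  iv <- pri$resid_var_prior
  free_load <- setdiff(spec$item_ids, spec$anchor_item)
  lp <- sum(stats::dnorm(c(params$loadings_within[free_load],
                           params$loadings_between[free_load],
                           params$intercepts),
                         li["mean"], sqrt(li["var"]), log = TRUE)) +
    sum(stats::dnorm(params_to_xi(params, spec$covariate_ids),
                     fe["mean"], sqrt(fe["var"]), log = TRUE)) +
    sum(dinvgamma_log(c(params$resid_var_within, params$resid_var_between),
                      iv["shape"], iv["rate"])) +
    dinvwishart_log(params$Sigma_b, pri$ranef_cov_prior$scale,
                    pri$ranef_cov_prior$df)
  ll + lp
}
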