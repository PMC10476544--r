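test_that("single-occasion, single-item likelihood matches the closed form", {
  y <- matrix(0.7, 1, 1)
  phi <- 0.4; s2 <- 0.5; tw <- 0.3
  ll <- within_marginal_loglik(y, lambda_w = 1, theta_w = tw,
                               phi = phi, innovation_var = s2)
  expect_equal(ll, dnorm(0.7, 0, sqrt(s2 / (1 - phi^2) + tw), log = TRUE),
               tolerance = 1e-12)
})

test_that("filtered likelihood equals the dense latent-marginalized normal", {
  set.seed(8)
  lw <- c(1, 0.8, 1.2); tw <- c(0.3, 0.5, 0.2)
  y <- matrix(rnorm(15), 5, 3)
  for (phi in c(-0.3, 0, 0.6, 0.95)) {
    for (s2 in c(0.2, 1.5)) {
      expect_equal(
        within_marginal_loglik(y, lw, tw, phi, s2),
        oracle_within_loglik(y, lw, tw, phi, s2),
        tolerance = 1e-8)
    }
  }
})

test_that("missing cells are skipped consistently with the dense oracle", {
  set.seed(9)
  lw <- c(1, 0.8, 1.2); tw <- c(0.3, 0.5, 0.2)
  y <- matrix(rnorm(18), 6, 3)
  y[2, 1] <- NA; y[4, ] <- NA; y[6, 3] <- NA
  expect_equal(within_marginal_loglik(y, lw, tw, 0.5, 0.7),
               oracle_within_loglik(y, lw, tw, 0.5, 0.7), tolerance = 1e-8)
})

test_that("phi = 0 reduces to independent factor-analysis densities", {
  set.seed(10)
  lw <- c(1, 0.9); tw <- c(0.4, 0.6); s2 <- 0.8
  y <- matrix(rnorm(8), 4, 2)
  per_row <- sum(vapply(seq_len(4), function(t) {
    oracle_within_loglik(y[t, , drop = FALSE], lw, tw, 0, s2)
  }, numeric(1)))
  expect_equal(within_marginal_loglik(y, lw, tw, 0, s2), per_row,
               tolerance = 1e-10)
})

test_that("likelihood is invariant to item permutation", {
  set.seed(11)
  lw <- c(1, 0.7, 1.4); tw <- c(0.2, 0.6, 0.4)
  y <- matrix(rnorm(12), 4, 3); y[3, 2] <- NA
  perm <- c(3, 1, 2)
  expect_equal(within_marginal_loglik(y, lw, tw, 0.5, 0.9),
               within_marginal_loglik(y[, perm], lw[perm], tw[perm], 0.5, 0.9),
               tolerance = 1e-12)
})

test_that("an all-missing occasion only propagates the state", {
  set.seed(12)
  lw <- c(1, 0.8); tw <- c(0.3, 0.5)
  y <- matrix(rnorm(10), 5, 2)
  y_aug <- rbind(y[1:3, ], NA, y[4:5, ])
  # inserting a fully missing occasion changes the implied lag between the
  # neighbours; the dense oracle with the same 6-occasion grid must agree
  expect_equal(within_marginal_loglik(y_aug, lw, tw, 0.6, 0.4),
               oracle_within_loglik(y_aug, lw, tw, 0.6, 0.4), tolerance = 1e-8)
})

test_that("nonstationary carryover is rejected", {
  y <- matrix(0, 2, 1)
  expect_error(within_marginal_loglik(y, 1, 0.5, 1.0, 0.5), "nonstationarity")
  expect_error(stationary_variance(1, 1), "nonstationarity")
})

test_that("default priors are diffuse and proper", {
  pri <- default_priors()
  expect_gte(unname(pri$loading_intercept_prior["var"]), 1e4)
  expect_gte(unname(pri$fixed_effect_prior["var"]), 1e4)
  # inverse-gamma mode b/(a+1) is strictly positive
  expect_gt(unname(pri$resid_var_prior["rate"] /
                     (pri$resid_var_prior["shape"] + 1)), 0)
  # df = dim + 2 makes the prior mean of Sigma_b equal the scale matrix
  expect_equal(pri$ranef_cov_prior$df, 5)
  expect_equal(pri$ranef_cov_prior$scale /
                 (pri$ranef_cov_prior$df - 3 - 1), diag(3))
})

test_that("joint log-posterior decomposes into likelihood plus priors", {
  sim <- quick_sim(n = 6, seed = 55, lengths = 4)
  params <- sim$params
  ranefs <- sim$random_effects
  spec <- dsem_model_spec(params$item_ids, anchor_item = params$anchor_item)
  lp1 <- joint_logposterior(params, ranefs, sim$panel, spec)

  # doubling prior variances changes only the prior term
  spec2 <- spec
  spec2$priors$loading_intercept_prior["var"] <- 2e6
  lp2 <- joint_logposterior(params, ranefs, sim$panel, spec2)
  delta <- sum(dnorm(c(params$loadings_within[setdiff(params$item_ids, params$anchor_item)],
                       params$loadings_between[setdiff(params$item_ids, params$anchor_item)],
                       params$intercepts), 0, sqrt(2e6), log = TRUE)) -
    sum(dnorm(c(params$loadings_within[setdiff(params$item_ids, params$anchor_item)],
                params$loadings_between[setdiff(params$item_ids, params$anchor_item)],
                params$intercepts), 0, sqrt(1e6), log = TRUE))
  expect_equal(lp2 - lp1, delta, tolerance = 1e-8)

  # non-positive-definite Sigma_b is a rejected state, not an exception
  bad <- params
  bad$Sigma_b <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)
  expect_identical(joint_logposterior(bad, ranefs, sim$panel, spec), -Inf)
})

test_that("with huge between residual variance the data stop informing eta_b", {
  sim <- quick_sim(n = 1, seed = 58, lengths = 5)
  params <- sim$params
  K <- length(params$item_ids)
  params$resid_var_between <- stats::setNames(rep(1e8, K), params$item_ids)
  spec <- dsem_model_spec(params$item_ids, anchor_item = params$anchor_item)
  ranefs <- sim$random_effects
  lps <- vapply(c(-2, 0, 2), function(e) {
    r <- ranefs; r$eta_b <- e
    joint_logposterior(params, r, sim$panel, spec) -
      dmvnorm_ref(c(e, r$phi, r$log_innovation_var), params)
  }, numeric(1))
  expect_lt(diff(range(lps)), 1e-3)
})

test_that("joint log-posterior agrees with a quadrature oracle", {
  # 1 person, T = 2, K = 1: integrate the two latent states and the
  # between item residual by 3-dimensional Gauss-Hermite quadrature
  p0 <- default_true_params()
  it <- p0$item_ids[1]
  params <- dsem_true_params(
    item_ids = it, anchor_item = it,
    loadings_within = c(1), loadings_between = c(1),
    intercepts = c(0.5), resid_var_within = c(0.4),
    resid_var_between = c(0.3),
    gamma = c(0, 0.5, log(0.6)), Sigma_b = diag(c(0.2, 0.05, 0.3)))
  df <- data.frame(person_id = "A", session = 1:2, x = c(1.1, 0.2))
  names(df)[3] <- it
  panel <- as_dsem_panel(df, it)
  spec <- dsem_model_spec(c(it, "dummy")[1:1], anchor_item = it)
  ranefs <- data.frame(person_id = "A", eta_b = 0.3, phi = 0.5,
                       log_innovation_var = log(0.6))

  gh <- function(nq = 40) {
    h <- pracma::gaussHermite(nq)
    s2 <- 0.6; phi <- 0.5
    sd1 <- sqrt(s2 / (1 - phi^2))
    # eta1 ~ N(0, sd1^2); eta2 | eta1 ~ N(phi eta1, s2); eb ~ N(0, 0.3)
    tot <- 0
    mu_b <- 0.5 + 1 * 0.3
    for (i in seq_len(nq)) for (j in seq_len(nq)) for (l in seq_len(nq)) {
      e1 <- sqrt(2) * sd1 * h$x[i]
      e2 <- phi * e1 + sqrt(2) * sqrt(s2) * h$x[j]
      eb <- sqrt(2) * sqrt(0.3) * h$x[l]
      lik <- dnorm(1.1, mu_b + eb + e1, sqrt(0.4)) *
        dnorm(0.2, mu_b + eb + e2, sqrt(0.4))
      tot <- tot + h$w[i] * h$w[j] * h$w[l] * lik
    }
    log(tot / pi^(3 / 2))
  }
  expect_equal(person_marginal_ref(panel, params, ranefs), gh(), tolerance = 1e-4)
})
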