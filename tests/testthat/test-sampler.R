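# hand-built PosteriorSamples-like object for summary/PSR unit checks
fake_samples <- function(chains, burn_in = 0L) {
  structure(list(chains = chains, burn_in = as.integer(burn_in), thin = 1L,
                 n_iterations = nrow(chains[[1]]),
                 settings = NULL, spec = NULL, n_persons = 0L),
            class = "dsem_samples")
}

test_that("settings are validated", {
  expect_error(mcmc_settings(n_iterations = 0), "positive")
  expect_error(mcmc_settings(n_iterations = 501), "even")
  expect_error(mcmc_settings(n_chains = 1), "chains")
  expect_error(mcmc_settings(rerun_multiplier = 2.5), "3, 4")
})

test_that("PSR matches a hand calculation and flags divergence", {
  c1 <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "gamma[phi]"))
  c2 <- matrix(c(2, 4, 4, 6), ncol = 1, dimnames = list(NULL, "gamma[phi]"))
  s <- fake_samples(list(c1, c2))
  W <- mean(c(var(c(1, 2, 3, 4)), var(c(2, 4, 4, 6))))
  B <- var(c(mean(c(1, 2, 3, 4)), mean(c(2, 4, 4, 6))))
  expect_equal(unname(compute_psr(s, "gamma[phi]")), sqrt((W + B) / W),
               tolerance = 1e-12)

  # identical chains give exactly 1
  s_id <- fake_samples(list(c1, c1))
  expect_identical(unname(compute_psr(s_id, "gamma[phi]")), 1)

  # well-separated chains give PSR far above 1
  set.seed(1)
  d1 <- matrix(rnorm(500, 0, 1), ncol = 1, dimnames = list(NULL, "gamma[phi]"))
  d2 <- matrix(rnorm(500, 5, 1), ncol = 1, dimnames = list(NULL, "gamma[phi]"))
  expect_gt(compute_psr(fake_samples(list(d1, d2)), "gamma[phi]"), 2)

  expect_error(compute_psr(fake_samples(list(c1)), "gamma[phi]"),
               "undefined-diagnostic")
})

test_that("posterior summaries are medians with equal-tailed 95% intervals", {
  c1 <- matrix(c(1, 2, 3, 4, 5), ncol = 1, dimnames = list(NULL, "nu[a]"))
  s <- fake_samples(list(c1, c1))
  sm <- summary(s)
  expect_equal(sm$point[sm$parameter == "nu[a]"], 3)

  set.seed(2)
  big <- matrix(rnorm(50000), ncol = 1, dimnames = list(NULL, "nu[a]"))
  big2 <- matrix(rnorm(50000), ncol = 1, dimnames = list(NULL, "nu[a]"))
  sm2 <- summary(fake_samples(list(big, big2)))
  expect_lt(abs(sm2$ci_low + 1.96), 0.02)
  expect_lt(abs(sm2$ci_high - 1.96), 0.02)
})

test_that("identical settings and seed reproduce chains bit-exactly", {
  sim <- quick_sim(n = 20, seed = 5, lengths = 6)
  spec <- dsem_model_spec(sim$params$item_ids,
                          anchor_item = sim$params$anchor_item)
  st <- quick_settings(n_iterations = 200)
  f1 <- run_mcmc(sim$panel, spec, st)
  f2 <- run_mcmc(sim$panel, spec, st)
  expect_identical(f1$chains, f2$chains)
})

test_that("stored derived contrasts equal their recomputation exactly", {
  sim <- quick_sim(n = 25, seed = 9, lengths = 6)
  spec <- dsem_model_spec(sim$params$item_ids,
                          anchor_item = sim$params$anchor_item)
  fit <- run_mcmc(sim$panel, spec, quick_settings(n_iterations = 400))
  ch <- fit$chains[[1]]
  for (it in sim$params$item_ids) {
    expect_identical(ch[, paste0("diff[", it, "]")],
                     ch[, paste0("lambda_b[", it, "]")] -
                       ch[, paste0("lambda_w[", it, "]")])
    expect_identical(ch[, paste0("ratio[", it, "]")],
                     ch[, paste0("lambda_b[", it, "]")] /
                       ch[, paste0("lambda_w[", it, "]")])
  }
  # correlations recomputed from stored covariance entries
  r <- ch[, "Sigma_b[3,2]"] / sqrt(ch[, "Sigma_b[2,2]"] * ch[, "Sigma_b[3,3]"])
  expect_equal(r, ch[, "r[phi,logvar]"], tolerance = 1e-12)
})

test_that("with no observations a free loading reproduces its prior", {
  # one item never observed: its within loading conditional is the prior
  sim <- quick_sim(n = 30, seed = 14, lengths = 8)
  df <- sim$panel$data
  blind <- sim$params$item_ids[4]
  df[[blind]] <- NA_real_
  panel <- as_dsem_panel(df, sim$params$item_ids)
  spec <- dsem_model_spec(sim$params$item_ids,
                          anchor_item = sim$params$anchor_item)
  fit <- run_mcmc(panel, spec, quick_settings(n_iterations = 3000))
  d <- retained_draws(fit, paste0("lambda_w[", blind, "]"))
  # prior normal(0, 1e6): draws are iid, so MC error of the mean is
  # 1000/sqrt(n_draws)
  expect_lt(abs(mean(d)), 4 * 1000 / sqrt(length(d)))
  expect_lt(abs(var(d) / 1e6 - 1), 0.2)
})

test_that("the residual-variance Gibbs conditional is the analytic inverse-gamma", {
  sim <- quick_sim(n = 40, seed = 23, lengths = 6)
  params <- sim$params
  states <- unlist(lapply(sim$trajectories, `[[`, "eta_w"))
  ini <- list(nu = unname(params$intercepts),
              lw = unname(params$loadings_within),
              lb = unname(params$loadings_between),
              tw = unname(params$resid_var_within),
              tb = unname(params$resid_var_between),
              m = unname(sim$person_item_means),
              states = states)
  spec <- dsem_model_spec(params$item_ids, anchor_item = params$anchor_item)
  st <- quick_settings(n_iterations = 8000)
  fit <- run_mcmc(sim$panel, spec, st, init = ini,
                  fix = list(lambda_w = TRUE, nu_lambda_b = TRUE,
                             theta_b = TRUE, eta_b = TRUE, phi_v = TRUE,
                             m = TRUE, states = TRUE, xi = TRUE,
                             sigma_b = TRUE))
  it1 <- params$item_ids[1]
  draws <- retained_draws(fit, paste0("theta_w[", it1, "]"), pool = FALSE)[[1]]
  # analytic conditional given the fixed latents
  y <- as.matrix(sim$panel$data[, it1])
  pidx <- match(sim$panel$data$person_id, sim$random_effects$person_id)
  resid <- y - sim$person_item_means[pidx, 1] -
    params$loadings_within[[1]] * states
  a_post <- 0.001 + length(resid) / 2
  b_post <- 0.001 + sum(resid^2) / 2
  ks <- suppressWarnings(stats::ks.test(1 / draws, stats::pgamma,
                                        shape = a_post, rate = b_post))
  expect_gt(ks$p.value, 0.001)
})

test_that("null carryover is recovered near zero", {
  p0 <- default_true_params()
  params <- dsem_true_params(p0$item_ids, p0$anchor_item, p0$loadings_within,
    p0$loadings_between, p0$intercepts, p0$resid_var_within,
    p0$resid_var_between, gamma = c(0, 0, -2),
    Sigma_b = diag(c(0.25, 1e-4, 0.2)))
  sim <- simulate_panel(params, n = 120, lengths = 12, seed = 61)
  spec <- dsem_model_spec(params$item_ids, anchor_item = params$anchor_item)
  fit <- run_mcmc(sim$panel, spec, quick_settings(n_iterations = 4000))
  g <- median(retained_draws(fit, "gamma[phi]"))
  expect_lt(abs(g), 0.05)
})

test_that("converge_and_rerun applies the extension multiplier", {
  sim <- quick_sim(n = 40, seed = 35, lengths = 10)
  spec <- dsem_model_spec(sim$params$item_ids,
                          anchor_item = sim$params$anchor_item)
  st <- mcmc_settings(n_iterations = 1000, seed = 7, psr_threshold = 1.3,
                      rerun_multiplier = 3, max_iterations = 8000)
  res <- converge_and_rerun(sim$panel, spec, st)
  first_ok <- res$history$n_iterations[match("rerun", res$history$stage) - 1L]
  expect_equal(res$final_iterations, 3L * first_ok)
  if (res$converged) {
    psr <- res$summary$psr[res$summary$monitored]
    expect_true(all(psr < st$psr_threshold))
  }
})

test_that("an exhausted iteration budget raises the convergence-failure flag", {
  sim <- quick_sim(n = 10, seed = 36, lengths = 3)
  spec <- dsem_model_spec(sim$params$item_ids,
                          anchor_item = sim$params$anchor_item)
  st <- mcmc_settings(n_iterations = 100, seed = 8, psr_threshold = 1.0001,
                      max_iterations = 200)
  expect_warning(res <- converge_and_rerun(sim$panel, spec, st),
                 "convergence failure")
  expect_false(res$converged)
  expect_s3_class(res$samples, "dsem_samples")
})

test_that("zero-length panels and invalid specs fail before sampling", {
  sim <- quick_sim(n = 10, seed = 41, lengths = 4)
  expect_error(dsem_model_spec(sim$params$item_ids, anchor_item = "nope"),
               "anchor_item")
  spec <- dsem_model_spec(sim$params$item_ids,
                          anchor_item = sim$params$anchor_item,
                          covariate_ids = "male")
  expect_error(run_mcmc(sim$panel, spec, quick_settings(n_iterations = 100)),
               "config error")
})
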