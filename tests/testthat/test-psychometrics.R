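# fake samples object with directly controlled draw columns
psy_fake <- function(draws_list, spec) {
  m <- do.call(cbind, draws_list)
  colnames(m) <- names(draws_list)
  structure(list(chains = list(m, m), burn_in = 0L, thin = 1L,
                 n_iterations = nrow(m), spec = spec,
                 settings = NULL, n_persons = 0L),
            class = "dsem_samples")
}

psy_cols <- function(item, lw, lb, tw, tb, veta, vbar, n = 200) {
  stats::setNames(
    list(rep(lw, n), rep(lb, n), rep(tw, n), rep(tb, n), rep(veta, n),
         rep(vbar, n)),
    c(paste0("lambda_w[", item, "]"), paste0("lambda_b[", item, "]"),
      paste0("theta_w[", item, "]"), paste0("theta_b[", item, "]"),
      "Sigma_b[1,1]", "vbar_w"))
}

test_that("stationary variance closed form and inverse check", {
  expect_identical(stationary_variance(0, 2.0), 2.0)
  expect_equal(stationary_variance(0.5, 1.0), 4 / 3, tolerance = 1e-12)
  # (0.9, 0.19) -> 1.0; a simulated series variance confirms the inverse
  expect_equal(stationary_variance(0.9, 0.19), 1.0, tolerance = 1e-12)
  traj <- simulate_latent_series(list(phi = 0.9, log_innovation_var = log(0.19)),
                                 T = 4e5, seed = 3)
  expect_lt(abs(var(traj$eta_w) - 1), 0.05)
})

test_that("symmetric variance split gives ICC one half", {
  spec <- dsem_model_spec(c("a", "b"), anchor_item = "a")
  s <- psy_fake(psy_cols("a", lw = 1, lb = 1, tw = 0, tb = 0,
                         veta = 0.4, vbar = 0.4), spec)
  expect_equal(unname(compute_icc(s, "a")["point"]), 0.5, tolerance = 1e-12)
})

test_that("reliability edge cases behave", {
  spec <- dsem_model_spec(c("a", "b"), anchor_item = "a")
  s0 <- psy_fake(psy_cols("a", 1, 1, tw = 0, tb = 0.3, veta = 0.4, vbar = 0.4),
                 spec)
  expect_equal(unname(compute_r2(s0, "a")$within["point"]), 1)
  s1 <- psy_fake(psy_cols("a", 0, 1, tw = 0.5, tb = 0.3, veta = 0.4,
                          vbar = 0.4), spec)
  expect_equal(unname(compute_r2(s1, "a")$within["point"]), 0)
})

test_that("difference test flags follow the interval-excludes-zero rule", {
  spec <- dsem_model_spec(c("a", "b"), anchor_item = "a")
  set.seed(4)
  # centered at .24 with sd .09: interval clear of zero -> noninvariant
  s <- psy_fake(list("diff[b]" = rnorm(4000, 0.242, 0.09)), spec)
  r <- loading_difference_test(s, "b")
  expect_false(r$invariant)
  # centered near zero -> invariant
  s2 <- psy_fake(list("diff[b]" = rnorm(4000, 0.03, 0.08)), spec)
  expect_true(loading_difference_test(s2, "b")$invariant)
  expect_error(loading_difference_test(s, "a"), "no-test")
})

test_that("correlations are summarized per draw, not from summarized pieces", {
  spec <- dsem_model_spec(c("a", "b"), anchor_item = "a")
  set.seed(5)
  n <- 4000
  # bimodal joint draws: the per-draw correlation median differs from the
  # correlation recomputed from marginal medians
  s22 <- c(rep(1, n / 2), rep(4, n / 2)) + runif(n, 0, 1e-3)
  s33 <- rep(1, n)
  s32 <- c(rep(0.9, n / 2), rep(-0.1, n / 2))
  cols <- list("Sigma_b[1,1]" = rep(1, n), "Sigma_b[2,1]" = rep(0, n),
               "Sigma_b[2,2]" = s22, "Sigma_b[3,1]" = rep(0, n),
               "Sigma_b[3,2]" = s32, "Sigma_b[3,3]" = s33,
               "r[phi,logvar]" = s32 / sqrt(s22 * s33),
               "r[eta_b,phi]" = rep(0, n), "r[eta_b,logvar]" = rep(0, n))
  s <- psy_fake(cols, spec)
  rc <- random_effect_correlations(s)
  per_draw <- median(s32 / sqrt(s22 * s33))
  expect_equal(rc$point[rc$correlation == "r[phi,zeta]"], per_draw,
               tolerance = 1e-10)
  med_based <- median(s32) / sqrt(median(s22) * median(s33))
  expect_gt(abs(med_based - per_draw), 0.1)
})

test_that("analytic and empirical psychometrics agree on a large panel", {
  # moderate carryover spread keeps every person well inside the
  # stationarity region, so the naive decomposition's finite-T bias stays
  # of order 1/T (with near-unit-root persons the person-mean centering
  # swallows slow state variation and the naive estimator breaks down; see
  # the methods vignette)
  p0 <- default_true_params()
  params <- dsem_true_params(p0$item_ids, p0$anchor_item,
    p0$loadings_within, p0$loadings_between, p0$intercepts,
    p0$resid_var_within, p0$resid_var_between,
    gamma = c(0, 0.35, -1.8),
    Sigma_b = build_sigma_ref(0.25, 0.02, 0.4, 0.5, 0.5, 0.2))
  sim <- simulate_panel(params, n = 500, lengths = 50, seed = 71)
  truth <- true_psychometrics(params, sim$random_effects)
  emp <- empirical_icc(sim$panel)
  expect_lt(max(abs(truth$icc - emp$icc)), 0.035)
})

test_that("fitted posteriors recover ICC and reliability of the truth", {
  params <- default_true_params()
  sim <- simulate_panel(params, n = 120, lengths = 12, seed = 81)
  spec <- dsem_model_spec(params$item_ids, anchor_item = params$anchor_item)
  fit <- run_mcmc(sim$panel, spec, quick_settings(n_iterations = 2500))
  truth <- true_psychometrics(params, sim$random_effects)
  tab <- item_psychometrics(fit)
  expect_true(all(tab$icc > 0 & tab$icc < 1))
  expect_true(all(tab$r2_within >= 0 & tab$r2_within <= 1))
  # posterior medians land near the realized-truth values for most items
  expect_lt(median(abs(tab$icc - truth$icc)), 0.12)
  expect_lt(median(abs(tab$r2_between - truth$r2_between)), 0.12)
  # anchor row conventions
  a <- tab[tab$item == params$anchor_item, ]
  expect_true(a$anchor)
  expect_true(is.na(a$difference))
  # decisions recomputed from stored loadings agree with stored contrasts
  for (it in setdiff(params$item_ids, params$anchor_item)) {
    d1 <- loading_difference_test(fit, it)
    lb <- retained_draws(fit, paste0("lambda_b[", it, "]"))
    lw <- retained_draws(fit, paste0("lambda_w[", it, "]"))
    qs <- quantile(lb - lw, c(0.025, 0.975), names = FALSE)
    expect_identical(unname(d1$invariant), qs[1] <= 0 && qs[2] >= 0)
  }
})

test_that("conditional effects table flags credible covariate effects", {
  spec <- dsem_model_spec(c("a", "b"), anchor_item = "a",
                          covariate_ids = "male")
  set.seed(6)
  cols <- list("beta[eta_b,male]" = rnorm(3000, -0.15, 0.05),
               "beta[phi,male]" = rnorm(3000, 0, 0.1),
               "beta[logvar,male]" = rnorm(3000, -0.24, 0.06))
  s <- psy_fake(cols, spec)
  ce <- conditional_effects(s, "male")
  expect_true(ce$credible[ce$target == "eta_b"])
  expect_false(ce$credible[ce$target == "phi"])
  expect_true(ce$credible[ce$target == "logvar"])
  expect_error(conditional_effects(s, "age"), "lookup error")
})

test_that("anchor selection finds the invariant set and honors forced anchors", {
  # fully invariant truth: loadings equal across levels
  p0 <- default_true_params()
  K <- length(p0$item_ids)
  lw <- p0$loadings_within
  params <- dsem_true_params(p0$item_ids, p0$anchor_item,
    loadings_within = lw, loadings_between = lw, intercepts = p0$intercepts,
    resid_var_within = p0$resid_var_within,
    resid_var_between = p0$resid_var_between * 2,
    gamma = p0$gamma, Sigma_b = p0$Sigma_b)
  sim <- simulate_panel(params, n = 120, lengths = 12, seed = 91)
  spec <- dsem_model_spec(params$item_ids, anchor_item = params$anchor_item)
  sel <- select_anchor(sim$panel, spec, quick_settings(n_iterations = 2000))
  # 21 pairwise 95% interval tests: a fully invariant truth yields a large
  # clique, but a stray exclusion among the weaker items is expected noise
  expect_gte(length(sel$invariant_set), K - 2L)
  expect_true(sel$anchor %in% sel$invariant_set)
  # ties broken by the highest within-level reliability
  r2w <- vapply(sel$invariant_set,
                function(it) compute_r2(sel$samples, it)$within[["point"]],
                numeric(1))
  expect_equal(sel$anchor, sel$invariant_set[which.max(r2w)])
  # user-forced anchors are honored by the final fit downstream
  forced <- dsem_model_spec(params$item_ids, anchor_item = p0$item_ids[3])
  expect_equal(forced$anchor_item, p0$item_ids[3])
  expect_error(select_anchor(sim$panel,
    dsem_model_spec(p0$item_ids[1:2], anchor_item = p0$item_ids[1]),
    quick_settings()), "at least 3")
})
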