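#' MCMC settings
#'
#' @param n_chains number of chains (>= 2; the potential scale reduction
#'   diagnostic is undefined for a single chain).
#' @param n_iterations iterations per chain (even; the first half is
#'   discarded as burn-in).
#' @param psr_threshold convergence cut-off for the largest monitored PSR
#'   (default 1.05).
#' @param rerun_multiplier after convergence at `I` iterations, the final
#'   run uses `rerun_multiplier * I` iterations (between 3 and 4) to guard
#'   against premature stoppage.
#' @param seed integer seed controlling all chains.
#' @param thin store every `thin`-th iteration (default 1: store everything).
#' @param adapt adapt per-person Metropolis scales during burn-in only
#'   (frozen afterwards, preserving detailed balance on the retained half).
#' @param max_iterations iteration budget for [converge_and_rerun()].
#' @return list of class `dsem_mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 2, n_iterations = 2000,
                          psr_threshold = 1.05, rerun_multiplier = 3,
                          seed = 1, thin = 1, adapt = TRUE,
                          max_iterations = 32000) {
  if (n_chains < 2) stop("settings error: n_chains must be >= 2", call. = FALSE)
  if (n_iterations <= 0) stop("settings error: n_iterations must be positive",
                              call. = FALSE)
  if (n_iterations %% 2L != 0L) stop("settings error: n_iterations must be even",
                                     call. = FALSE)
  if (psr_threshold <= 1) stop("settings error: psr_threshold must exceed 1",
                               call. = FALSE)
  if (rerun_multiplier < 3 || rerun_multiplier > 4) {
    stop("settings error: rerun_multiplier must lie in [3, 4]", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 psr_threshold = psr_threshold,
                 rerun_multiplier = rerun_multiplier,
                 seed = as.integer(seed), thin = as.integer(thin),
                 adapt = isTRUE(adapt),
                 max_iterations = as.integer(max_iterations)),
            class = "dsem_mcmc_settings")
}

# column names of the stored draw matrix
draw_names <- function(item_ids, covariate_ids) {
  K <- length(item_ids)
  p <- length(covariate_ids)
  nm <- c(paste0("nu[", item_ids, "]"),
          paste0("lambda_w[", item_ids, "]"),
          paste0("lambda_b[", item_ids, "]"),
          paste0("theta_w[", item_ids, "]"),
          paste0("theta_b[", item_ids, "]"),
          "gamma[phi]", "gamma[logvar]")
  if (p > 0) {
    nm <- c(nm, paste0("beta[eta_b,", covariate_ids, "]"),
            paste0("beta[phi,", covariate_ids, "]"),
            paste0("beta[logvar,", covariate_ids, "]"))
  }
  c(nm,
    "Sigma_b[1,1]", "Sigma_b[2,1]", "Sigma_b[2,2]",
    "Sigma_b[3,1]", "Sigma_b[3,2]", "Sigma_b[3,3]",
    paste0("diff[", item_ids, "]"),
    paste0("ratio[", item_ids, "]"),
    "r[phi,logvar]", "r[eta_b,phi]", "r[eta_b,logvar]",
    "vbar_w")
}

# monitored set for convergence control: structural + measurement
# parameters, not person effects or derived transforms
monitored_parameters <- function(samples) {
  nm <- colnames(samples$chains[[1]])
  nm[grepl("^(nu|lambda_w|lambda_b|theta_w|theta_b|gamma|beta|Sigma_b)\\[",
           nm)]
}

# data arrays for the C++ core, persons in first-appearance order
prepare_arrays <- function(panel, spec) {
  df <- panel$data
  ids <- unique(df$person_id)
  if (!all(spec$item_ids %in% names(df))) {
    stop("config error: panel lacks configured item column(s): ",
         paste(setdiff(spec$item_ids, names(df)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(spec$covariate_ids %in% names(df))) {
    stop("config error: panel lacks configured covariate column(s): ",
         paste(setdiff(spec$covariate_ids, names(df)), collapse = ", "),
         call. = FALSE)
  }
  y <- as.matrix(df[, spec$item_ids, drop = FALSE])
  pidx <- match(df$person_id, ids)
  len <- as.integer(table(pidx)[as.character(seq_along(ids))])
  start <- cumsum(c(0L, len[-length(len)]))
  X <- if (length(spec$covariate_ids)) {
    as.matrix(df[match(ids, df$person_id), spec$covariate_ids, drop = FALSE])
  } else {
    matrix(0, length(ids), 0)
  }
  list(y = y, start = as.integer(start), len = as.integer(len),
       X = X, person_ids = ids,
       anchor = match(spec$anchor_item, spec$item_ids) - 1L)
}

# moment-based initial values with chain-specific overdispersion; called
# with the chain's RNG stream active
make_init <- function(arr, spec, overdisperse = TRUE) {
  y <- arr$y
  K <- ncol(y)
  n <- length(arr$len)
  p <- ncol(arr$X)
  jit <- function(sd) if (overdisperse) stats::rnorm(1, 0, sd) else 0
  jitv <- function(m, sd) if (overdisperse) stats::rnorm(m, 0, sd) else numeric(m)

  ybar <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    rows <- arr$start[i] + seq_len(arr$len[i])
    ybar[i, ] <- colMeans(y[rows, , drop = FALSE], na.rm = TRUE)
  }
  nu0 <- colMeans(ybar, na.rm = TRUE)
  nu0[!is.finite(nu0)] <- 0
  for (k in seq_len(K)) ybar[!is.finite(ybar[, k]), k] <- nu0[k]
  eta0 <- rowMeans(sweep(ybar, 2, nu0, "-"))
  dev <- y - ybar[rep(seq_len(n), arr$len), , drop = FALSE]
  vw <- apply(dev, 2, stats::var, na.rm = TRUE)
  vw[!is.finite(vw) | vw <= 0] <- 0.5
  vb <- apply(ybar, 2, stats::var)
  vb[!is.finite(vb) | vb <= 0] <- 0.25

  anchor1 <- arr$anchor + 1L
  lw0 <- 1 + jitv(K, 0.25); lw0[anchor1] <- 1
  lb0 <- 1 + jitv(K, 0.25); lb0[anchor1] <- 1
  phi0 <- pmin(0.95, pmax(-0.95, jit(0.25) + jitv(n, 0.1)))
  v0 <- log(pmax(mean(vw) * 0.3, 1e-3)) + jit(0.7) + jitv(n, 0.3)
  xi0 <- c(mean(phi0), mean(v0), jitv(3 * p, 0.1))
  list(nu = nu0 + jitv(K, 0.2),
       lw = lw0, lb = lb0,
       tw = pmax(vw * 0.6 * exp(jit(0.4)), 1e-4),
       tb = pmax(vb * 0.5 * exp(jit(0.4)), 1e-4),
       u = cbind(eta0 + jitv(n, 0.1), phi0, v0),
       m = ybar,
       xi = xi0,
       Sigma = diag(c(max(stats::var(eta0), 0.05), 0.1, 1)) * exp(jit(0.4)),
       states = rep(0, nrow(y)),
       mh_scale = rep(1, n))
}

default_fix <- function() {
  list(lambda_w = FALSE, theta_w = FALSE, nu_lambda_b = FALSE,
       theta_b = FALSE, eta_b = FALSE, phi_v = FALSE, m = FALSE,
       states = FALSE, xi = FALSE, sigma_b = FALSE)
}

#' Run the multi-chain Gibbs sampler
#'
#' Estimates the two-level dynamic factor model on a validated panel.
#' Chains start from independently over-dispersed moment-based initial
#' values; each chain's randomness is a deterministic function of
#' `settings$seed`, so identical settings reproduce chains bit-exactly.
#' Derived contrasts (cross-level loading differences and ratios,
#' random-effect correlations, and the person-average stationary within
#' variance) are recorded per retained draw.
#'
#' @param panel a `dsem_panel`.
#' @param spec a [dsem_model_spec()].
#' @param settings a [mcmc_settings()] list.
#' @param store_ranef also store per-person random-effect draws (3 x n per
#'   iteration; off by default).
#' @param init optional named list overriding initial values (chain-shared);
#'   entries as in the internal initializer.
#' @param fix optional named list of logical flags freezing update blocks at
#'   their initial values (`lambda_w`, `theta_w`, `nu_lambda_b`, `theta_b`,
#'   `eta_b`, `phi_v`, `m`, `states`, `xi`, `sigma_b`); used for
#'   block-conditional validation.
#' @return Object of class `dsem_samples`: per-chain draw matrices, burn-in
#'   bookkeeping, acceptance diagnostics, and the model/settings metadata.
#' @export
run_mcmc <- function(panel, spec, settings, store_ranef = FALSE,
                     init = NULL, fix = list()) {
  stopifnot(inherits(panel, "dsem_panel"), inherits(spec, "dsem_model_spec"),
            inherits(settings, "dsem_mcmc_settings"))
  arr <- prepare_arrays(panel, spec)
  pri <- spec$priors
  priors_cpp <- list(
    li_mean = unname(pri$loading_intercept_prior["mean"]),
    li_var = unname(pri$loading_intercept_prior["var"]),
    fe_mean = unname(pri$fixed_effect_prior["mean"]),
    fe_var = unname(pri$fixed_effect_prior["var"]),
    ig_shape = unname(pri$resid_var_prior["shape"]),
    ig_rate = unname(pri$resid_var_prior["rate"]),
    iw_scale = pri$ranef_cov_prior$scale,
    iw_df = pri$ranef_cov_prior$df)
  fix_full <- utils::modifyList(default_fix(), fix)
  control <- list(n_iter = settings$n_iterations, thin = settings$thin,
                  adapt = settings$adapt,
                  burn_in = settings$n_iterations %/% 2L,
                  store_ranef = isTRUE(store_ranef))
  nm <- draw_names(spec$item_ids, spec$covariate_ids)

  chains <- vector("list", settings$n_chains)
  diag_list <- vector("list", settings$n_chains)
  ranef <- if (store_ranef) vector("list", settings$n_chains) else NULL
  for (ch in seq_len(settings$n_chains)) {
    chain_seed <- (settings$seed + 77003L * (ch - 1L)) %% .Machine$integer.max
    set.seed(chain_seed)
    ini <- make_init(arr, spec, overdisperse = TRUE)
    if (!is.null(init)) ini <- utils::modifyList(ini, init)
    res <- .dsem_gibbs(arr$y, arr$start, arr$len, arr$X, arr$anchor,
                       priors_cpp, ini, control, fix_full)
    draws <- res$draws
    colnames(draws) <- nm
    chains[[ch]] <- draws
    diag_list[[ch]] <- list(accept_rate = res$accept_rate,
                            phi_rejections = res$phi_rejections)
    if (store_ranef) ranef[[ch]] <- res$ranef_draws
  }
  structure(list(chains = chains,
                 burn_in = settings$n_iterations %/% 2L,
                 thin = settings$thin,
                 n_iterations = settings$n_iterations,
                 settings = settings, spec = spec,
                 person_ids = arr$person_ids,
                 n_persons = length(arr$person_ids),
                 diagnostics = diag_list,
                 ranef = ranef),
            class = "dsem_samples")
}

#' Retained (post burn-in) draws of one parameter
#'
#' @param samples a `dsem_samples` object.
#' @param parameter stored parameter name (see `colnames` of a chain).
#' @param pool pool chains into one vector (default) or return a list.
#' @return numeric vector (or list of per-chain vectors).
#' @export
retained_draws <- function(samples, parameter, pool = TRUE) {
  keep <- samples$burn_in %/% samples$thin
  out <- lapply(samples$chains, function(ch) {
    if (!parameter %in% colnames(ch)) {
      stop("lookup error: no stored parameter '", parameter, "'", call. = FALSE)
    }
    ch[(keep + 1L):nrow(ch), parameter]
  })
  if (pool) unlist(out, use.names = FALSE) else out
}

#' Potential scale reduction diagnostic
#'
#' For each monitored parameter, computes `sqrt((W + B) / W)` on the
#' retained (second) halves, where `W` is the mean within-chain variance and
#' `B` the between-chain variance of the chain means. Chains with identical
#' retained draws give exactly 1; diverging chains give values far above 1.
#'
#' @param samples a `dsem_samples` object (>= 2 chains).
#' @param parameters parameter names (default: all monitored measurement and
#'   structural parameters).
#' @return named numeric vector of PSR values.
#' @export
compute_psr <- function(samples, parameters = monitored_parameters(samples)) {
  if (length(samples$chains) < 2L) {
    stop("undefined-diagnostic error: PSR requires at least two chains",
         call. = FALSE)
  }
  keep <- samples$burn_in %/% samples$thin
  vapply(parameters, function(par) {
    per <- lapply(samples$chains, function(ch) ch[(keep + 1L):nrow(ch), par])
    W <- mean(vapply(per, stats::var, numeric(1)))
    B <- stats::var(vapply(per, mean, numeric(1)))
    if (W <= 0) return(if (B <= 0) 1 else Inf)
    sqrt((W + B) / W)
  }, numeric(1))
}

#' Summarize the posterior
#'
#' Posterior medians and equal-tailed 95% credible intervals (2.5th/97.5th
#' percentiles of the pooled retained draws), with the PSR diagnostic
#' attached for monitored parameters.
#'
#' @param object a `dsem_samples` object.
#' @param ... unused.
#' @return data.frame of class `dsem_summary` with columns `parameter`,
#'   `point` (median), `ci_low`, `ci_high`, `psr`, `monitored`.
#' @export
summary.dsem_samples <- function(object, ...) {
  nm <- colnames(object$chains[[1]])
  psr <- compute_psr(object)
  rows <- lapply(nm, function(par) {
    d <- retained_draws(object, par)
    qs <- stats::quantile(d, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    data.frame(parameter = par, point = qs[2], ci_low = qs[1], ci_high = qs[3],
               psr = if (par %in% names(psr)) psr[[par]] else NA_real_,
               monitored = par %in% names(psr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dsem_summary", "data.frame")
  out
}

#' @rdname summary.dsem_samples
#' @param samples a `dsem_samples` object.
#' @export
summarize_posterior <- function(samples) summary(samples)

#' Run to convergence, then re-run at an extended iteration count
#'
#' Runs the sampler, checks the largest monitored PSR against the
#' threshold, and doubles the iteration count until convergence or until
#' `max_iterations` is exhausted. After convergence at `I` iterations the
#' model is re-estimated once at `rerun_multiplier * I` iterations (guarding
#' against premature stoppage) and that final run is summarized. If the
#' budget is exhausted, or the final run itself fails the PSR criterion, the
#' best attempt is returned with `converged = FALSE` — never a silent
#' success.
#'
#' @param panel a `dsem_panel`.
#' @param spec a [dsem_model_spec()].
#' @param settings a [mcmc_settings()] list (`n_iterations` is the starting
#'   count; `max_iterations` the budget).
#' @param store_ranef store per-person draws in the final run.
#' @return list with `samples` (final `dsem_samples`), `summary`,
#'   `converged` (logical), `final_iterations`, and `history` (data.frame of
#'   iteration counts and max PSR per attempt).
#' @export
converge_and_rerun <- function(panel, spec, settings, store_ranef = FALSE) {
  it <- settings$n_iterations
  history <- data.frame(n_iterations = integer(0), max_psr = numeric(0),
                        stage = character(0))
  run <- NULL
  converged_at <- NA_integer_
  while (it <= settings$max_iterations) {
    s <- settings; s$n_iterations <- as.integer(it)
    run <- run_mcmc(panel, spec, s, store_ranef = store_ranef)
    mp <- max(compute_psr(run))
    history <- rbind(history, data.frame(n_iterations = it, max_psr = mp,
                                         stage = "search"))
    if (mp < settings$psr_threshold) { converged_at <- it; break }
    it <- it * 2L
  }
  if (is.na(converged_at)) {
    warning("convergence failure: PSR criterion not met within the ",
            "iteration budget; returning best attempt", call. = FALSE)
    return(list(samples = run, summary = summary(run), converged = FALSE,
                final_iterations = run$n_iterations, history = history))
  }
  final_it <- as.integer(ceiling(converged_at * settings$rerun_multiplier / 2) * 2)
  s <- settings; s$n_iterations <- final_it
  final <- run_mcmc(panel, spec, s, store_ranef = store_ranef)
  mp <- max(compute_psr(final))
  history <- rbind(history, data.frame(n_iterations = final_it, max_psr = mp,
                                       stage = "rerun"))
  converged <- mp < settings$psr_threshold
  if (!converged) {
    warning("convergence failure: extended re-run exceeded the PSR threshold",
            call. = FALSE)
  }
  list(samples = final, summary = summary(final), converged = converged,
       final_iterations = final_it, history = history)
}

#' @export
print.dsem_samples <- function(x, ...) {
  cat(sprintf("dsem_samples: %d chains x %d iterations (burn-in %d), %d persons\n",
              length(x$chains), x$n_iterations, x$burn_in, x$n_persons))
  invisible(x)
}

#' @export
print.dsem_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  for (col in intersect(c("point", "ci_low", "ci_high", "psr"), names(df))) {
    df[[col]] <- round(df[[col]], digits)
  }
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
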