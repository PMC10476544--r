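#' Stationary variance of the within-person latent AR(1) process
#'
#' `innovation_var / (1 - phi^2)`, the time-constant latent state variance
#' under stationarity.
#'
#' @param phi carryover, `|phi| < 1` (vectorized).
#' @param innovation_var positive innovation variance (vectorized).
#' @return stationary variance(s).
#' @export
stationary_variance <- function(phi, innovation_var) {
  if (any(abs(phi) >= 1)) {
    stop("nonstationarity error: |phi| >= 1 has no stationary variance",
         call. = FALSE)
  }
  if (any(innovation_var <= 0)) {
    stop("parameter error: innovation_var must be positive", call. = FALSE)
  }
  innovation_var / (1 - phi^2)
}

# equal-tailed 95% summary of a draw vector
draw_summary <- function(d) {
  qs <- stats::quantile(d, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  c(point = qs[2], ci_low = qs[1], ci_high = qs[3])
}

# per-draw item variance components; mode "ranef" plugs in the per-draw
# person-average stationary latent variance, mode "fixed" the
# fixed-effects-only plug-in exp(gamma_v + V_v/2) / (1 - gamma_phi^2 - V_phi)
item_variance_draws <- function(samples, item, mode = c("ranef", "fixed")) {
  mode <- match.arg(mode)
  lw <- retained_draws(samples, paste0("lambda_w[", item, "]"))
  lb <- retained_draws(samples, paste0("lambda_b[", item, "]"))
  tw <- retained_draws(samples, paste0("theta_w[", item, "]"))
  tb <- retained_draws(samples, paste0("theta_b[", item, "]"))
  veta <- retained_draws(samples, "Sigma_b[1,1]")
  vw <- if (mode == "ranef") {
    retained_draws(samples, "vbar_w")
  } else {
    gphi <- retained_draws(samples, "gamma[phi]")
    gv <- retained_draws(samples, "gamma[logvar]")
    vphi <- retained_draws(samples, "Sigma_b[2,2]")
    vv <- retained_draws(samples, "Sigma_b[3,3]")
    exp(gv + vv / 2) / pmax(1 - gphi^2 - vphi, 1e-8)
  }
  list(between_common = lb^2 * veta, between_resid = tb,
       within_common = lw^2 * vw, within_resid = tw)
}

#' Posterior intraclass correlation of one item
#'
#' Per retained draw, the between-level item variance is
#' `lambda_b^2 Var(eta_b) + theta_b` and the within-level variance
#' `lambda_w^2 Vbar_w + theta_w`, where `Vbar_w` is the person-average
#' stationary latent variance computed from that draw's person-specific
#' carryover and innovation variance. The ICC is the between share of the
#' total; it is summarized by the posterior median and equal-tailed 95%
#' credible interval.
#'
#' @param samples a `dsem_samples` object.
#' @param item item id.
#' @param mode `"ranef"` (default, person-average plug-in respecting
#'   random-effect heterogeneity) or `"fixed"` (fixed-effects-only plug-in).
#' @return named numeric `point, ci_low, ci_high`.
#' @export
compute_icc <- function(samples, item, mode = "ranef") {
  v <- item_variance_draws(samples, item, mode)
  b <- v$between_common + v$between_resid
  w <- v$within_common + v$within_resid
  draw_summary(b / (b + w))
}

#' Posterior level-specific reliability (R-squared) of one item
#'
#' Per draw: `r2_between = lambda_b^2 Var(eta_b) / (lambda_b^2 Var(eta_b) +
#' theta_b)` and `r2_within = lambda_w^2 Vbar_w / (lambda_w^2 Vbar_w +
#' theta_w)`; the proportion of each level's item variance explained by
#' that level's latent factor.
#'
#' @inheritParams compute_icc
#' @return list with elements `within` and `between`, each
#'   `point, ci_low, ci_high`.
#' @export
compute_r2 <- function(samples, item, mode = "ranef") {
  v <- item_variance_draws(samples, item, mode)
  if (all(v$within_common + v$within_resid <= 0) ||
      all(v$between_common + v$between_resid <= 0)) {
    stop("undefined-ratio error: zero total variance", call. = FALSE)
  }
  list(within = draw_summary(v$within_common / (v$within_common + v$within_resid)),
       between = draw_summary(v$between_common / (v$between_common + v$between_resid)))
}

#' Cross-level loading-difference test for one item
#'
#' Summarizes the per-draw contrast `lambda_b - lambda_w`. The item is
#' flagged noninvariant when the equal-tailed 95% credible interval of the
#' difference excludes zero (the bolding rule of the measurement table); no
#' multiplicity correction is applied.
#'
#' @param samples a `dsem_samples` object.
#' @param item a non-anchor item id.
#' @return list `difference` (point + CI), `invariant` (logical).
#' @export
loading_difference_test <- function(samples, item) {
  if (identical(item, samples$spec$anchor_item)) {
    stop("no-test error: the anchor item's difference is fixed at 0 by ",
         "constraint", call. = FALSE)
  }
  d <- draw_summary(retained_draws(samples, paste0("diff[", item, "]")))
  list(difference = d,
       invariant = d["ci_low"] <= 0 && d["ci_high"] >= 0)
}

#' Random-effect correlations
#'
#' Per retained draw, the random-effect covariance is converted to the
#' three correlations among carryover (`phi`), log innovation variance
#' (`zeta`) and the trait factor (`eta_b`), then summarized.
#'
#' @param samples a `dsem_samples` object.
#' @return data.frame with rows `r[phi,zeta]`, `r[phi,eta_b]`,
#'   `r[zeta,eta_b]` and columns `point, ci_low, ci_high, credible`.
#' @export
random_effect_correlations <- function(samples) {
  map <- c("r[phi,zeta]" = "r[phi,logvar]",
           "r[phi,eta_b]" = "r[eta_b,phi]",
           "r[zeta,eta_b]" = "r[eta_b,logvar]")
  rows <- lapply(names(map), function(lbl) {
    s <- draw_summary(retained_draws(samples, map[[lbl]]))
    data.frame(correlation = lbl, point = s["point"], ci_low = s["ci_low"],
               ci_high = s["ci_high"],
               credible = s["ci_low"] > 0 || s["ci_high"] < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate effects from a conditional fit
#'
#' Posterior medians and 95% credible intervals of the covariate's effects
#' on the trait factor, the carryover, and the log innovation variance. In
#' the conditional model, the `gamma` intercept rows of the summary are the
#' reference-group means (dummy = 0).
#'
#' @param samples a `dsem_samples` object from a conditional fit.
#' @param covariate covariate name.
#' @return data.frame with rows for `eta_b`, `phi`, `logvar` effects and a
#'   `credible` flag (CI excludes zero).
#' @export
conditional_effects <- function(samples, covariate) {
  cols <- paste0("beta[", c("eta_b", "phi", "logvar"), ",", covariate, "]")
  if (!all(cols %in% colnames(samples$chains[[1]]))) {
    stop("lookup error: covariate '", covariate,
         "' was not part of the fitted model", call. = FALSE)
  }
  rows <- lapply(seq_along(cols), function(j) {
    s <- draw_summary(retained_draws(samples, cols[j]))
    data.frame(target = c("eta_b", "phi", "logvar")[j],
               point = s["point"], ci_low = s["ci_low"], ci_high = s["ci_high"],
               credible = s["ci_low"] > 0 || s["ci_high"] < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-item measurement table
#'
#' Assembles the measurement-model report: ICC, level-specific loadings and
#' reliability, and the cross-level difference test per item. The anchor
#' row carries fixed loadings of 1 and no difference test.
#'
#' @param samples a `dsem_samples` object.
#' @param mode ICC/R2 plug-in mode, see [compute_icc()].
#' @return data.frame of class `dsem_measurement`, one row per item.
#' @export
item_psychometrics <- function(samples, mode = "ranef") {
  spec <- samples$spec
  rows <- lapply(spec$item_ids, function(it) {
    icc <- compute_icc(samples, it, mode)
    r2 <- compute_r2(samples, it, mode)
    lw <- draw_summary(retained_draws(samples, paste0("lambda_w[", it, "]")))
    lb <- draw_summary(retained_draws(samples, paste0("lambda_b[", it, "]")))
    anchor <- identical(it, spec$anchor_item)
    if (anchor) {
      diff <- c(point = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      inv <- NA
    } else {
      dt <- loading_difference_test(samples, it)
      diff <- dt$difference
      inv <- dt$invariant
    }
    data.frame(item = it, anchor = anchor,
               icc = icc["point"],
               loading_within = lw["point"], r2_within = r2$within["point"],
               loading_between = lb["point"], r2_between = r2$between["point"],
               difference = diff["point"],
               diff_ci_low = diff["ci_low"], diff_ci_high = diff["ci_high"],
               invariant = inv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dsem_measurement", "data.frame")
  out
}

#' Structural parameter table
#'
#' Summarizes the structural block of a fit: carryover mean and variance,
#' log innovation-variance mean and variance, trait-factor variance, the
#' three random-effect correlations, and (for conditional fits) the
#' covariate effect rows.
#'
#' @param samples a `dsem_samples` object.
#' @return data.frame with `parameter, point, ci_low, ci_high, credible`.
#' @export
structural_summary <- function(samples) {
  base <- c("phi_mean" = "gamma[phi]", "phi_var" = "Sigma_b[2,2]",
            "zeta_mean" = "gamma[logvar]", "zeta_var" = "Sigma_b[3,3]",
            "eta_b_var" = "Sigma_b[1,1]",
            "r_phi_zeta" = "r[phi,logvar]", "r_phi_eta" = "r[eta_b,phi]",
            "r_zeta_eta" = "r[eta_b,logvar]")
  rows <- lapply(names(base), function(lbl) {
    s <- draw_summary(retained_draws(samples, base[[lbl]]))
    data.frame(parameter = lbl, point = s["point"], ci_low = s["ci_low"],
               ci_high = s["ci_high"],
               credible = s["ci_low"] > 0 || s["ci_high"] < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (cv in samples$spec$covariate_ids) {
    ce <- conditional_effects(samples, cv)
    ce <- data.frame(parameter = paste0("beta_", ce$target, "_x_", cv),
                     point = ce$point, ci_low = ce$ci_low,
                     ci_high = ce$ci_high, credible = ce$credible,
                     stringsAsFactors = FALSE)
    out <- rbind(out, ce)
  }
  rownames(out) <- NULL
  out
}

#' Data-driven anchor selection (adapted triangle heuristic)
#'
#' Runs a provisional fit with a reference item fixed to 1 at both levels,
#' computes per draw the cross-level loading ratio `lambda_b_k / lambda_w_k`
#' for every item, and tests each item pair's ratio contrast against zero
#' with an equal-tailed 95% credible interval. Pairs whose contrast interval
#' contains zero are mutually invariant; the mutual-invariance graph's
#' largest clique (exhaustive search, K <= 10) is the invariant set, and the
#' member with the highest within-level reliability is returned as the
#' anchor for the final fit. Ratios are scale-free, so the choice of the
#' provisional reference does not bias the contrasts.
#'
#' @param panel a `dsem_panel`.
#' @param spec a [dsem_model_spec()]; `spec$anchor_item` is used as the
#'   provisional reference.
#' @param settings a [mcmc_settings()] list for the provisional fit.
#' @return list with `anchor` (item id), `invariant_set` (the clique),
#'   `pairs` (data.frame of pairwise contrasts) and `samples` (provisional
#'   fit).
#' @export
select_anchor <- function(panel, spec, settings) {
  K <- length(spec$item_ids)
  if (K < 3L) stop("anchor selection requires at least 3 items", call. = FALSE)
  fit <- run_mcmc(panel, spec, settings)
  ratios <- sapply(spec$item_ids,
                   function(it) retained_draws(fit, paste0("ratio[", it, "]")))
  r2w <- vapply(spec$item_ids, function(it) {
    compute_r2(fit, it)$within["point"]
  }, numeric(1))

  pairs <- t(utils::combn(K, 2))
  adj <- matrix(FALSE, K, K)
  pair_rows <- vector("list", nrow(pairs))
  for (idx in seq_len(nrow(pairs))) {
    j <- pairs[idx, 1]; k <- pairs[idx, 2]
    d <- ratios[, j] - ratios[, k]
    qs <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
    inv <- qs[1] <= 0 && qs[2] >= 0
    adj[j, k] <- adj[k, j] <- inv
    pair_rows[[idx]] <- data.frame(
      item_j = spec$item_ids[j], item_k = spec$item_ids[k],
      contrast_low = qs[1], contrast_high = qs[2], invariant = inv,
      stringsAsFactors = FALSE)
  }

  # exhaustive maximum-clique search over the K-item graph
  best <- integer(0)
  best_r2 <- -Inf
  for (code in seq_len(2^K - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(K) - 1)) > 0)
    if (length(members) < length(best)) next
    ok <- TRUE
    if (length(members) > 1L) {
      cmb <- utils::combn(members, 2)
      ok <- all(adj[cbind(cmb[1, ], cmb[2, ])])
    }
    if (!ok) next
    top <- max(r2w[members])
    if (length(members) > length(best) ||
        (length(members) == length(best) && top > best_r2)) {
      best <- members
      best_r2 <- top
    }
  }
  if (length(best) < 2L) {
    stop("no-invariant-set error: no mutually invariant item pair found; ",
         "a defended difference table cannot be produced", call. = FALSE)
  }
  anchor <- spec$item_ids[best[which.max(r2w[best])]]
  list(anchor = anchor, invariant_set = spec$item_ids[best],
       pairs = do.call(rbind, pair_rows), samples = fit)
}

#' Psychometric quantities implied by generating parameters
#'
#' The analytic counterpart of [compute_icc()]/[compute_r2()] for a known
#' truth. When realized random effects are supplied, the person-average
#' stationary within variance and the trait variance are computed over
#' those persons (the estimand the posterior plug-in targets); otherwise
#' population values are used (`Sigma_b[1,1]` and the fixed-effects
#' plug-in within variance).
#'
#' @param params a [dsem_true_params()] object.
#' @param ranefs optional realized random effects from [simulate_panel()].
#' @return data.frame with per-item `icc`, `r2_within`, `r2_between`, and
#'   attribute `vbar_w`.
#' @export
true_psychometrics <- function(params, ranefs = NULL) {
  if (is.null(ranefs)) {
    g <- params$gamma; S <- params$Sigma_b
    vbar <- exp(g[3] + S[3, 3] / 2) / (1 - g[2]^2 - S[2, 2])
    veta <- S[1, 1]
  } else {
    vbar <- mean(stationary_variance(ranefs$phi,
                                     exp(ranefs$log_innovation_var)))
    veta <- mean(ranefs$eta_b^2) - mean(ranefs$eta_b)^2
  }
  lw <- params$loadings_within; lb <- params$loadings_between
  tw <- params$resid_var_within; tb <- params$resid_var_between
  b <- lb^2 * veta + tb
  w <- lw^2 * vbar + tw
  out <- data.frame(item = params$item_ids,
                    icc = unname(b / (b + w)),
                    r2_within = unname(lw^2 * vbar / w),
                    r2_between = unname(lb^2 * veta / b),
                    stringsAsFactors = FALSE)
  attr(out, "vbar_w") <- unname(vbar)
  out
}

#' Naive empirical variance decomposition of a panel
#'
#' Per item: the between variance is the variance across persons of the
#' person means, the within variance the pooled variance of within-person
#' deviations. The ratio approximates the ICC up to bias terms of order
#' 1/T-bar (person means contain within noise).
#'
#' @param panel a `dsem_panel`.
#' @return data.frame with per-item `var_between`, `var_within`, `icc`.
#' @export
empirical_icc <- function(panel) {
  persons <- panel_person_split(panel)
  K <- length(panel$item_ids)
  pm <- t(vapply(persons, function(p) colMeans(p$y, na.rm = TRUE), numeric(K)))
  vb <- apply(pm, 2, stats::var, na.rm = TRUE)
  dev <- do.call(rbind, lapply(persons, function(p) {
    sweep(p$y, 2, colMeans(p$y, na.rm = TRUE), "-")
  }))
  vw <- apply(dev, 2, function(col) {
    col <- col[!is.na(col)]
    sum(col^2) / (length(col) - length(persons))
  })
  data.frame(item = panel$item_ids, var_between = unname(vb),
             var_within = unname(vw), icc = unname(vb / (vb + vw)),
             stringsAsFactors = FALSE)
}
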