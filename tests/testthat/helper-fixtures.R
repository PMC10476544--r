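# shared fixture builders for the test suite; everything is generated in
# code under fixed seeds

toy_panel_df <- function() {
  data.frame(
    person_id = c("A", "A", "A", "B", "B", "C"),
    session = c(1, 2, 3, 1, 2, 1),
    it1 = c(1.2, 0.8, 1.0, 2.0, 2.2, 0.5),
    it2 = c(0.9, 1.1, NA, 1.8, 2.1, 0.4),
    stringsAsFactors = FALSE)
}

# small simulated panel for fast end-to-end fits
quick_sim <- function(n = 60, seed = 421, lengths = length_distribution(),
                      params = default_true_params(), ...) {
  simulate_panel(params, n = n, lengths = lengths, seed = seed, ...)
}

quick_settings <- function(n_iterations = 1200, seed = 99, ...) {
  mcmc_settings(n_iterations = n_iterations, seed = seed, ...)
}

build_sigma_ref <- function(ve, vp, vv, r_pe, r_ve, r_pv) {
  dsemcfa:::build_sigma_b(ve, vp, vv, r_pe, r_ve, r_pv)
}

# sum of per-person marginal log densities (states and between residuals
# integrated out), via the package's dense-covariance construction
person_marginal_ref <- function(panel, params, ranefs) {
  persons <- dsemcfa:::panel_person_split(panel)
  sum(vapply(seq_along(persons), function(i) {
    dsemcfa:::person_marginal_loglik(persons[[i]]$y, params,
                                     ranefs$eta_b[i], ranefs$phi[i],
                                     exp(ranefs$log_innovation_var[i]))
  }, numeric(1)))
}

# random-effect multivariate-normal log density under the generating truth
dmvnorm_ref <- function(u, params) {
  dsemcfa:::dmvnorm_log(u, params$gamma, params$Sigma_b)
}

# dense-covariance oracle for the within-level marginal likelihood:
# builds the full TK x TK latent-marginalized normal covariance explicitly
oracle_within_loglik <- function(y, lambda_w, theta_w, phi, innovation_var) {
  Tn <- nrow(y); K <- ncol(y)
  g0 <- innovation_var / (1 - phi^2)
  Gam <- g0 * phi^abs(outer(seq_len(Tn), seq_len(Tn), "-"))
  obs <- which(!is.na(t(y)))
  tt <- rep(seq_len(Tn), each = K)[obs]
  kk <- rep(seq_len(K), times = Tn)[obs]
  V <- outer(lambda_w[kk], lambda_w[kk]) * Gam[tt, tt, drop = FALSE] +
    diag(theta_w[kk], length(obs))
  r <- as.vector(t(y))[obs]
  -0.5 * length(r) * log(2 * pi) -
    0.5 * as.numeric(determinant(V, logarithm = TRUE)$modulus) -
    0.5 * sum(r * solve(V, r))
}
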