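# shared fixtures, all built in code

# random positive-definite correlation matrix
rand_corr <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  stats::cov2cor(crossprod(A) / (p + 2))
}

# small multi-country synthetic study for fast tests
small_study <- function(seed = 1, n_countries = 6, n = 1000, tau = 0.12, ...) {
  cfg <- country_configs(countries = paste0("C", seq_len(n_countries)),
                         n = rep(n, n_countries), seed = seed, ...)
  suppressWarnings(simulate_study(configs = cfg, tau = tau, seed = seed))
}

# a magna_fit-shaped stub with prescribed edge weights and covariance,
# for exercising the bootstrap in controlled settings
stub_magna <- function(omega, vcov_omega, alpha = 0.05) {
  net <- ggm_network(omega)
  net$pvals <- matrix(0, nrow(omega), ncol(omega))
  diag(net$pvals) <- 1
  net <- threshold_network(net, alpha)
  structure(list(network = net, vcov_omega = vcov_omega, alpha = alpha),
            class = "magna_fit")
}
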