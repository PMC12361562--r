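test_that("off-diagonal vectorization is lossless and canonically ordered", {
  expect_equal(vech_offdiag(diag(12)), rep(0, 66), ignore_attr = TRUE)
  expect_length(vech_offdiag(diag(12)), 66)
  R <- flourish_total_correlations()
  expect_equal(unvech_offdiag(vech_offdiag(R), colnames(R)), R)
  om <- pooled_truth("reported")
  expect_equal(unvech_offdiag(vech_offdiag(om), colnames(om), diag_value = 0), om)
  expect_error(unvech_offdiag(rep(0, 65)), "p\\(p-1\\)/2")
})

test_that("sampling covariance of correlations matches closed forms", {
  # p = 2: Var(r) = (1 - rho^2)^2 / n
  R2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(corr_sampling_cov(R2, 100)[1, 1], 0.75^2 / 100, tolerance = 1e-12)
  V <- corr_sampling_cov(diag(4), 250)
  expect_equal(V, diag(6) / 250, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("sampling covariance matches the Monte-Carlo covariance of sample correlations", {
  Rt <- corr_from_pcor(pooled_truth("random", p = 4, density = 0.5, seed = 7))
  n <- 500
  set.seed(11)
  ys <- replicate(10000, vech_offdiag(cor(MASS::mvrnorm(n, rep(0, 4), Rt))))
  Vmc <- cov(t(ys))
  Vth <- corr_sampling_cov(Rt, n)
  # tolerances from the Monte-Carlo error at 10,000 sims plus O(1/n) bias
  expect_lt(max(abs(Vmc - Vth)), 1e-4)
  expect_lt(max(abs(diag(Vmc) / diag(Vth) - 1)), 0.05)
})

test_that("identical groups favour the pooled saturated model", {
  R <- rand_corr(12, 5)
  dimnames(R) <- list(sfm_item_codes(), sfm_item_codes())
  cs <- correlation_set(list(R, R), n = c(800, 800), countries = c("A", "B"))
  het <- fit_saturated_models(cs)
  expect_equal(het$chisq_pooled, 0, tolerance = 1e-9)
  expect_equal(het$preferred_aic, "pooled")
  expect_equal(het$preferred_bic, "pooled")
  expect_error(fit_saturated_models(cs[1, ]), "at least 2")
})

test_that("heterogeneous groups favour the single-country saturated model", {
  st <- small_study(seed = 12, n_countries = 6, n = 2000, tau = 0.12)
  het <- fit_saturated_models(build_correlation_set(st))
  expect_gt(het$chisq_pooled, 0)
  expect_equal(het$preferred_aic, "single")
  expect_equal(het$preferred_bic, "single")
})

test_that("with tau fixed at zero MAGNA reduces to the common structure", {
  R <- rand_corr(12, 6)
  dimnames(R) <- list(sfm_item_codes(), sfm_item_codes())
  cs <- correlation_set(list(R, R, R), n = c(500, 700, 900),
                        countries = c("A", "B", "C"))
  mg <- fit_magna(cs, fix_tau = 0)
  expect_equal(unname(mg$rho), vech_offdiag(R), tolerance = 1e-6, ignore_attr = TRUE)

  # single-country degenerate call equals that country's saturated GGM
  mg1 <- fit_magna(cs[1, ], fix_tau = 0)
  expect_equal(mg1$network$omega_raw, pcor_from_corr(R), tolerance = 1e-6)
  expect_error(fit_magna(cs[1:2, ]), "fewer than 3")
})

test_that("estimates are invariant to country ordering", {
  st <- small_study(seed = 13, n_countries = 5, n = 1500)
  cs <- build_correlation_set(st)
  mg1 <- fit_magna(cs)
  mg2 <- fit_magna(cs[c(4, 2, 5, 1, 3), ])
  expect_equal(mg1$rho, mg2$rho, tolerance = 1e-8)
  expect_equal(mg1$tau, mg2$tau, tolerance = 1e-6)
})

test_that("tau is estimated near zero when countries are homogeneous", {
  st <- small_study(seed = 14, n_countries = 8, n = 3000, tau = 0,
                    missing_rate = 0, weight_dispersion = 0)
  mg <- fit_magna(build_correlation_set(st))
  expect_lt(mg$mean_tau, 0.02)
})

test_that("MAGNA agrees with univariate random-effects meta-analysis per edge", {
  skip_if_not_installed("metafor")
  st <- small_study(seed = 15, n_countries = 12, n = 4000)
  cs <- build_correlation_set(st)
  mg <- fit_magna(cs)
  V0 <- corr_sampling_cov(corr_from_pcor(st$truth$pooled_partials), 1)
  ymat <- sapply(cs$R, vech_offdiag)
  uni <- vapply(1:66, function(j) {
    f <- metafor::rma(yi = ymat[j, ], vi = diag(V0)[j] / cs$n, method = "ML")
    c(sqrt(f$tau2), unname(stats::coef(f)))
  }, numeric(2))
  # univariate fits ignore cross-edge sampling correlation, so agreement is
  # approximate but should be tight on both scales
  expect_lt(max(abs(mg$tau - uni[1, ])), 0.02)
  expect_lt(max(abs(mg$rho - uni[2, ])), 0.01)
})

test_that("delta-method edge SEs match a nonparametric bootstrap over countries", {
  cfgs <- country_configs(countries = paste0("C", 1:50), n = rep(1500, 50),
                          missing_rate = 0, weight_dispersion = 0, seed = 21)
  st <- suppressWarnings(simulate_study(configs = cfgs, tau = 0.12, seed = 21))
  cs <- build_correlation_set(st)
  mg <- fit_magna(cs)
  set.seed(31)
  boots <- replicate(120, {
    idx <- sample.int(50, replace = TRUE)
    bs <- correlation_set(cs$R[idx], cs$n[idx], countries = paste0("B", 1:50))
    fit_magna(bs)$edges$weight
  })
  ratio <- mg$edges$se / apply(boots, 1, sd)
  expect_lt(abs(stats::median(ratio) - 1), 0.10)
})

test_that("random-effect summary is complete, sorted, and degenerate-safe", {
  st <- small_study(seed = 16, n_countries = 6, n = 1200)
  mg <- fit_magna(build_correlation_set(st))
  tab <- random_effect_summary(mg)
  expect_equal(nrow(tab), 66)
  expect_equal(tab$tau, sort(tab$tau, decreasing = TRUE))
  expect_equal(attr(tab, "mean"), mean(mg$tau))

  R <- rand_corr(12, 8); dimnames(R) <- list(sfm_item_codes(), sfm_item_codes())
  cs0 <- correlation_set(list(R, R, R), n = rep(600, 3), countries = c("A", "B", "C"))
  mg0 <- fit_magna(cs0, fix_tau = 0)
  tab0 <- random_effect_summary(mg0)
  expect_true(all(tab0$tau == 0))
  expect_equal(attr(tab0, "max"), 0)
})

test_that("the spread of per-edge tau estimates shrinks with more countries", {
  est <- vapply(c(22, 100), function(C) {
    cfg <- country_configs(countries = paste0("C", 1:C), n = rep(1200, C),
                           missing_rate = 0, weight_dispersion = 0, seed = C)
    st <- suppressWarnings(simulate_study(configs = cfg, tau = 0.1, seed = C,
                                          pooled = pooled_truth("random", p = 12,
                                                                density = 0.3, seed = 2)))
    sd(fit_magna(build_correlation_set(st))$tau)
  }, numeric(1))
  expect_lt(est[2], est[1])
})
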