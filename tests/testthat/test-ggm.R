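test_that("partial correlations match the recursive formula", {
  expect_equal(pcor_from_corr(diag(5)), matrix(0, 5, 5), ignore_attr = TRUE)

  # three variables, all pairwise r = 0.5: partial = (0.5 - 0.25)/(1 - 0.25)
  R3 <- matrix(0.5, 3, 3); diag(R3) <- 1
  om <- pcor_from_corr(R3)
  expect_equal(om[upper.tri(om)], rep(1 / 3, 3), tolerance = 1e-12)

  # the financial-domain edge of the published total-sample matrix is close
  # to the pooled-network value (the two matrices legitimately differ)
  om_tot <- pcor_from_corr(flourish_total_correlations())
  expect_lt(abs(om_tot["E", "WS"] - 0.650), 0.05)

  expect_error(pcor_from_corr(matrix(c(1, 1, 1, 1), 2)), "positive definite")
})

test_that("corr_from_pcor inverts pcor_from_corr", {
  expect_equal(corr_from_pcor(matrix(0, 4, 4)), diag(4), ignore_attr = TRUE)

  om2 <- matrix(c(0, 0.5, 0.5, 0), 2)   # two nodes: partial equals marginal
  expect_equal(corr_from_pcor(om2)[1, 2], 0.5, tolerance = 1e-12)

  R <- flourish_total_correlations()
  expect_equal(corr_from_pcor(pcor_from_corr(R)), R, tolerance = 1e-10)
  for (seed in 1:8) {
    Rr <- rand_corr(6, seed)
    expect_equal(corr_from_pcor(pcor_from_corr(Rr)), Rr, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("permuting nodes permutes pcor, EI and predictability consistently", {
  R <- rand_corr(6, 21)
  perm <- c(3, 1, 6, 2, 5, 4)
  om <- pcor_from_corr(R)
  expect_equal(pcor_from_corr(R[perm, perm]), om[perm, perm], ignore_attr = TRUE)
  expect_equal(expected_influence(om[perm, perm]), expected_influence(om)[perm],
               ignore_attr = TRUE)
  expect_equal(predictability(R[perm, perm]), predictability(R)[perm],
               ignore_attr = TRUE)
})

test_that("predictability is invariant to sign-flipping a variable", {
  R <- rand_corr(5, 22)
  flip <- diag(c(1, -1, 1, 1, -1))
  expect_equal(predictability(flip %*% R %*% flip), predictability(R),
               ignore_attr = TRUE)
})

test_that("edge p-values follow the partial-correlation t-test", {
  om <- matrix(0, 12, 12)
  expect_equal(edge_pvalues(om, 100)[1, 2], 1)

  om[1, 2] <- om[2, 1] <- 0.1
  expect_lt(edge_pvalues(om, 1000)[1, 2], 0.05)   # t ~ 3.16
  expect_gt(edge_pvalues(om, 100)[1, 2], 0.05)
  # oracle: direct t-distribution computation at n = 1000, k = 10
  tval <- 0.1 * sqrt(988 / (1 - 0.01))
  expect_equal(edge_pvalues(om, 1000)[1, 2], 2 * pt(-tval, 988), tolerance = 1e-12)
})

test_that("thresholding zeroes non-significant edges without refitting", {
  om <- matrix(0, 3, 3)
  om[1, 2] <- om[2, 1] <- 0.4
  om[1, 3] <- om[3, 1] <- 0.2
  pv <- matrix(1, 3, 3)
  pv[1, 2] <- pv[2, 1] <- 0.01
  pv[1, 3] <- pv[3, 1] <- 0.06
  net <- ggm_network(om)
  net$pvals <- pv
  thr <- threshold_network(net, 0.05)
  expect_equal(sum(thr$retained[upper.tri(thr$retained)]), 1)
  expect_equal(thr$omega[1, 3], 0)
  expect_equal(thr$omega[1, 2], 0.4)
  expect_equal(thr$omega_raw, net$omega)   # original weights preserved

  all_in <- threshold_network(`$<-`(net, "pvals", matrix(0.001, 3, 3)), 0.05)
  expect_equal(all_in$omega, net$omega)
  none <- threshold_network(`$<-`(net, "pvals", matrix(0.5, 3, 3)), 0.05)
  expect_true(all(none$omega == 0))
})

test_that("Gaussian discrepancy has its closed-form values", {
  S <- rand_corr(4, 31)
  d0 <- gaussian_discrepancy(S, S, 500)
  expect_equal(d0$F, 0, tolerance = 1e-12)
  expect_equal(d0$chisq, 0, tolerance = 1e-9)

  # p = 2, S with r = 0.5 against the identity: F = -log(det(S)) = -log(0.75)
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  d <- gaussian_discrepancy(S2, diag(2), 101)
  expect_equal(d$F, -log(0.75), tolerance = 1e-12)
  expect_equal(d$chisq, -100 * log(0.75), tolerance = 1e-10)

  d2 <- gaussian_discrepancy(S2, diag(2), 201)
  expect_equal(d2$chisq / d$chisq, 200 / 100)   # linear in n - 1
})

test_that("fit indices behave at the exact-fit and zero-df limits", {
  ix <- fit_indices(chisq = 39, df = 39, chisq_baseline = 5000, df_baseline = 66,
                    n = 1000, loglik = -100, n_params = 39)
  expect_equal(ix$rmsea, 0)
  expect_equal(ix$cfi, 1)
  expect_equal(ix$aic, 200 + 78)
  expect_equal(ix$bic, 200 + 39 * log(1000))

  sat <- fit_indices(chisq = 0, df = 0, chisq_baseline = 5000, df_baseline = 66,
                     n = 1000, loglik = -100, n_params = 78)
  expect_equal(sat$rmsea, 0)
  expect_equal(sat$cfi, 1)
  expect_true(is.na(sat$tli) && is.na(sat$rfi))
})

test_that("expected influence is the signed row sum", {
  expect_equal(expected_influence(matrix(0, 4, 4)), rep(0, 4), ignore_attr = TRUE)
  om <- matrix(0, 3, 3)
  om[1, 2] <- om[2, 1] <- 0.3
  om[1, 3] <- om[3, 1] <- -0.1
  expect_equal(expected_influence(om), c(0.2, 0.3, -0.1), ignore_attr = TRUE)
  # row sums equal column sums by symmetry
  net <- pooled_truth("reported")
  expect_equal(expected_influence(net), colSums(net))
  expect_lt(abs(expected_influence(net)["LS"] - 1.010), 0.05)
})

test_that("predictability equals regression R-squared", {
  expect_equal(predictability(diag(5)), rep(0, 5), ignore_attr = TRUE)
  R2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(predictability(R2), c(0.36, 0.36), ignore_attr = TRUE)

  # least-squares oracle on random 5-node systems
  for (seed in 1:5) {
    R <- rand_corr(5, 40 + seed)
    set.seed(seed)
    x <- MASS::mvrnorm(20000, rep(0, 5), R, empirical = TRUE)
    r2_lm <- vapply(1:5, function(i) {
      summary(lm(x[, i] ~ x[, -i]))$r.squared
    }, numeric(1))
    expect_equal(predictability(R), r2_lm, tolerance = 1e-8, ignore_attr = TRUE)
  }
})
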