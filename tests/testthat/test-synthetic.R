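test_that("item schema has 12 items, two per domain, 0-10 range", {
  items <- sfm_items()
  expect_equal(nrow(items), 12)
  expect_equal(as.integer(table(items$domain_id)), rep(2L, 6))
  expect_equal(anyDuplicated(items$code), 0L)
})

test_that("pooled_truth sources behave as specified", {
  # published network carries the expected strongest within-domain edges
  rep_net <- pooled_truth("reported")
  expect_equal(rep_net["E", "WS"], 0.650)
  expect_equal(rep_net["C", "SR"], 0.550)
  expect_equal(diag(rep_net), rep(0, 12), ignore_attr = TRUE)
  expect_gt(min(eigen(corr_from_pcor(rep_net), symmetric = TRUE,
                      only.values = TRUE)$values), 0)

  # empty network implies the identity correlation
  z <- pooled_truth("zero")
  expect_true(all(z == 0))
  expect_equal(corr_from_pcor(z), diag(12), ignore_attr = TRUE)

  # random: requested edge count, PD implied matrix by eigen check
  rn <- pooled_truth("random", p = 4, density = 0.5, seed = 3)
  expect_equal(sum(rn[upper.tri(rn)] != 0), 3)
  expect_gt(min(eigen(corr_from_pcor(rn), symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_identical(rn, pooled_truth("random", p = 4, density = 0.5, seed = 3))
})

test_that("degenerate random effects reproduce the pooled marginals exactly", {
  om <- pooled_truth("random", p = 5, density = 0.5, seed = 2)
  R0 <- corr_from_pcor(om)
  cc <- perturb_country_structures(om, 0, 4, seed = 1)
  for (R in cc) expect_equal(R, R0, tolerance = 1e-12)
  expect_equal(attr(cc, "proj_dist"), rep(0, 4))
})

test_that("per-edge spread of perturbed structures matches tau (Monte-Carlo oracle)", {
  om <- pooled_truth("random", p = 6, density = 0.4, seed = 5)
  cc <- perturb_country_structures(om, 0.12, 2000, seed = 9)
  sds <- apply(sapply(cc, vech_offdiag), 1, sd)
  # MC tolerance at 2000 draws (se of an SD ~ tau/sqrt(2*1999) ~ 0.002),
  # plus a small allowance for the rare PD projection
  expect_true(all(abs(sds - 0.12) < 0.01))
  expect_lt(mean(attr(cc, "proj_dist") > 1e-10), 0.05)
})

test_that("perturbation is seed-deterministic", {
  om <- pooled_truth("reported")
  a <- suppressWarnings(perturb_country_structures(om, 0.12, 1, seed = 4))
  b <- suppressWarnings(perturb_country_structures(om, 0.12, 1, seed = 4))
  expect_identical(a[[1]], b[[1]])
})

test_that("nearest-PD projection is idempotent and unit-diagonal", {
  R <- rand_corr(6, 11)
  expect_equal(nearest_pd_corr(R), R, ignore_attr = TRUE, tolerance = 1e-14)
  expect_equal(attr(nearest_pd_corr(R), "proj_dist"), 0)
  broken <- R; broken[1, 2] <- broken[2, 1] <- 0.999
  fixed <- nearest_pd_corr(broken)
  expect_gt(min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(fixed), rep(1, 6), ignore_attr = TRUE)
})

test_that("generated samples converge to the target correlation at large n", {
  R <- corr_from_pcor(pooled_truth("random", p = 5, density = 0.5, seed = 6))
  cfg <- list(country = "X", n = 100000, missing_rate = 0,
              weight_dispersion = 0, seed = 8)
  d <- generate_country_data(R, cfg)
  emp <- cor(as.matrix(d[, -(1:2)]))
  expect_lt(max(abs(emp - R)), 0.01)
  expect_true(all(d$weight == 1))
})

test_that("missingness lands at the configured MCAR rate", {
  R <- diag(12); dimnames(R) <- list(sfm_item_codes(), sfm_item_codes())
  cfg <- list(country = "X", n = 20000, missing_rate = 0.017,
              weight_dispersion = 0.5, seed = 13)
  d <- generate_country_data(R, cfg)
  frac <- mean(is.na(as.matrix(d[, sfm_item_codes()])))
  # binomial tolerance: 4 * sqrt(p(1-p)/(20000*12))
  expect_lt(abs(frac - 0.017), 4 * sqrt(0.017 * 0.983 / (20000 * 12)))
  expect_equal(mean(d$weight), 1, tolerance = 1e-12)
  expect_error(generate_country_data(matrix(c(1, 2, 2, 1), 2), cfg), "positive definite")
})

test_that("whole studies are reproducible bitwise from the seed", {
  s1 <- small_study(seed = 5, n_countries = 3, n = 200)
  s2 <- small_study(seed = 5, n_countries = 3, n = 200)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$configs), 3)
  expect_true(all(s1$configs$missing_rate >= 0.001 & s1$configs$missing_rate <= 0.017))
})

test_that("study CSV export writes one sample per country plus ground truth", {
  st <- small_study(seed = 6, n_countries = 2, n = 120)
  dir <- withr::local_tempdir()
  write_study_csv(st, dir)
  expect_length(list.files(dir, pattern = "^sample_"), 2)
  expect_length(list.files(dir, pattern = "^truth_corr_"), 2)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  expect_equal(truth$seed, 6)
  expect_equal(unlist(truth$pooled_partials),
               as.vector(t(st$truth$pooled_partials)), ignore_attr = TRUE)
})
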