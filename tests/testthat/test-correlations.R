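make_sample <- function(n, seed = 1, missing_cells = 0) {
  set.seed(seed)
  x <- matrix(runif(n * 12, 0, 10), n, 12, dimnames = list(NULL, sfm_item_codes()))
  d <- dplyr::bind_cols(tibble::tibble(country = "X", weight = rep(1, n)),
                        tibble::as_tibble(x))
  d
}

test_that("listwise deletion counts dropped rows correctly", {
  d <- make_sample(10)
  out <- listwise_complete(d, min_rows = 5)
  expect_identical(out, structure(d, n_dropped = 0L), ignore_attr = TRUE)
  expect_equal(attr(out, "n_dropped"), 0)

  d2 <- d
  d2$H[1] <- NA; d2$LS[4] <- NA; d2$WS[9] <- NA
  out2 <- listwise_complete(d2, min_rows = 5)
  expect_equal(nrow(out2), 7)
  expect_equal(attr(out2, "n_dropped"), 3)
  expect_false(anyNA(out2[sfm_item_codes()]))

  expect_error(listwise_complete(d2[1:6, ], min_rows = 5), "X")
})

test_that("dropped fraction under MCAR matches the binomial prediction", {
  R <- diag(12); dimnames(R) <- list(sfm_item_codes(), sfm_item_codes())
  cfg <- list(country = "X", n = 10000, missing_rate = 0.01,
              weight_dispersion = 0, seed = 3)
  d <- generate_country_data(R, cfg)
  out <- listwise_complete(d)
  p_drop <- 1 - (1 - 0.01)^12
  expect_lt(abs(attr(out, "n_dropped") / 10000 - p_drop),
            4 * sqrt(p_drop * (1 - p_drop) / 10000))
})

test_that("weighted correlations reduce to Pearson with equal weights", {
  d <- make_sample(200, seed = 2)
  R <- weighted_correlation_matrix(d)
  expect_equal(R, cor(as.matrix(d[sfm_item_codes()])), ignore_attr = TRUE,
               tolerance = 1e-14)
  expect_equal(attr(R, "n"), 200)
})

test_that("weighted correlation follows the direct formula on toy data", {
  d <- tibble::tibble(x = c(0, 1, 2, 3), y = c(0, 1, 2, 3), weight = c(2, 1, 1, 3))
  R <- weighted_correlation_matrix(d, items = c("x", "y"))
  expect_equal(R["x", "y"], 1)   # perfect collinearity at any positive weights

  d2 <- tibble::tibble(x = c(0, 1, 2, 3), y = c(0, 1, 1, 0), weight = c(1, 1, 1, 1))
  expect_equal(weighted_correlation_matrix(d2, items = c("x", "y"))["x", "y"], 0)
  d2$weight <- c(5, 1, 1, 5)     # symmetric weights keep the orthogonality
  expect_equal(weighted_correlation_matrix(d2, items = c("x", "y"))["x", "y"], 0)
})

test_that("correlations are invariant to rescaling all weights", {
  d <- make_sample(150, seed = 4)
  set.seed(5); d$weight <- rexp(150) + 0.1
  R1 <- weighted_correlation_matrix(d)
  d$weight <- d$weight * 37.5
  R2 <- weighted_correlation_matrix(d)
  expect_equal(R1, R2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(R1 - t(R1))), 1e-12)
  expect_equal(diag(R1), rep(1, 12), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("kish flag reports the effective rather than nominal sample size", {
  d <- make_sample(100, seed = 6)
  set.seed(7); d$weight <- rlnorm(100, 0, 0.5)
  n_kish <- attr(weighted_correlation_matrix(d, kish = TRUE), "n")
  expect_lt(n_kish, 100)
  expect_equal(n_kish, sum(d$weight)^2 / sum(d$weight^2))
})

test_that("degenerate inputs fail with informative errors", {
  d <- make_sample(100, seed = 8)
  d$MH <- 5
  expect_error(weighted_correlation_matrix(d), "MH")
  d2 <- make_sample(100, seed = 9)
  d2$H[3] <- NA
  expect_error(weighted_correlation_matrix(d2), "listwise")
})

test_that("correlation sets preserve country order and propagate errors", {
  st <- small_study(seed = 7, n_countries = 4, n = 400)
  cs <- build_correlation_set(st)
  expect_s3_class(cs, "correlation_set")
  expect_equal(cs$country, paste0("C", 1:4))
  expect_true(all(cs$n + cs$n_dropped == 400))
  for (R in cs$R) {
    expect_lt(max(abs(R - t(R))), 1e-12)
    expect_equal(diag(R), rep(1, 12), ignore_attr = TRUE, tolerance = 1e-12)
  }

  one <- build_correlation_set(st$data[st$data$country == "C1", ])
  expect_equal(nrow(one), 1)

  bad <- st$data
  bad$H[bad$country == "C2"] <- 5
  expect_error(build_correlation_set(bad), "C2")
})

test_that("correlation sets round-trip losslessly through CSV", {
  st <- small_study(seed = 8, n_countries = 3, n = 300)
  cs <- build_correlation_set(st)
  dir <- withr::local_tempdir()
  write_correlation_set(cs, dir)
  back <- read_correlation_set(dir)
  expect_equal(back$country, cs$country)
  expect_equal(back$n, cs$n)
  for (i in 1:3) expect_equal(back$R[[i]], cs$R[[i]], tolerance = 1e-12)

  # orphan matrix file not listed in the manifest is an error
  file.copy(file.path(dir, "corr_C1.csv"), file.path(dir, "corr_ZZ.csv"))
  expect_error(read_correlation_set(dir), "manifest")
})
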