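# Published summary statistics from the 22-country flourishing study
# (Global Flourishing Study Wave 1 secondary analysis). The raw microdata
# are access-restricted; these printed matrices and tables are the only
# study quantities shipped with the package and serve as fixtures,
# defaults for the synthetic generator, and inputs for arithmetic checks.

.flourish_matrix_raw <- function() {
  codes <- sfm_item_codes()
  # rows: lower triangle = total-sample weighted correlations,
  #        upper triangle = pooled MAGNA edge weights (partial correlations)
  x <- c(
    1.000, 0.410, 0.120, 0.085, 0.030, 0.170, 0.026, 0.011, 0.039, 0.071, 0.038, 0.030,
    0.657, 1.000, 0.078, 0.047, 0.001, 0.260,-0.008, 0.012, 0.028, 0.075, 0.066, 0.043,
    0.513, 0.466, 1.000, 0.310, 0.120, 0.080, 0.091, 0.018, 0.071, 0.039, 0.001, 0.021,
    0.437, 0.387, 0.561, 1.000, 0.025, 0.052, 0.061, 0.058, 0.000, 0.014, 0.048, 0.014,
    0.433, 0.407, 0.519, 0.393, 1.000, 0.190, 0.150, 0.120, 0.130, 0.075, 0.008, 0.009,
    0.580, 0.603, 0.515, 0.426, 0.523, 1.000, 0.099, 0.029, 0.039, 0.033, 0.010, 0.013,
    0.363, 0.339, 0.432, 0.358, 0.477, 0.430, 1.000, 0.270, 0.061, 0.031,-0.008,-0.004,
    0.289, 0.259, 0.329, 0.300, 0.395, 0.334, 0.464, 1.000, 0.033, 0.027,-0.006, 0.000,
    0.456, 0.443, 0.482, 0.359, 0.517, 0.474, 0.418, 0.336, 1.000, 0.550, 0.003, 0.009,
    0.462, 0.461, 0.465, 0.357, 0.494, 0.467, 0.390, 0.309, 0.731, 1.000, 0.015, 0.016,
    0.300, 0.326, 0.232, 0.210, 0.162, 0.254, 0.110, 0.086, 0.196, 0.206, 1.000, 0.650,
    0.278, 0.301, 0.210, 0.185, 0.140, 0.237, 0.097, 0.069, 0.181, 0.189, 0.734, 1.000
  )
  matrix(x, 12, 12, byrow = TRUE, dimnames = list(codes, codes))
}

#' Published pooled flourishing network edge weights
#'
#' The pooled cross-national network of the 12 flourishing items: partial
#' correlations estimated by random-effects meta-analytic Gaussian network
#' aggregation over 22 country samples, as published for the
#' Global Flourishing Study Wave 1 (upper-diagonal edge weights).
#'
#' @return A symmetric 12x12 matrix of partial correlations with zero
#'   diagonal, item codes as dimnames.
#' @seealso [flourish_total_correlations()], [pooled_truth()]
#' @examples
#' flourish_pooled_edges()["E", "WS"]  # 0.650
#' @export
flourish_pooled_edges <- function() {
  m <- .flourish_matrix_raw()
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  m
}

#' Published total-sample weighted correlation matrix
#'
#' The sample-weighted Pearson correlation matrix of the 12 flourishing
#' items over the pooled total sample of N = 202,898 respondents from 22
#' countries (lower-diagonal values of the published matrix).
#'
#' @return A symmetric 12x12 correlation matrix with unit diagonal.
#' @export
flourish_total_correlations <- function() {
  m <- .flourish_matrix_raw()
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Published per-country sample sizes
#'
#' Post-deletion analysed sample sizes of the 22 Global Flourishing Study
#' Wave 1 country samples (total N = 202,898). Used as the default country
#' sizes of the synthetic study generator.
#'
#' @return A named integer vector of length 22.
#' @export
flourish_country_sizes <- function() {
  c(Argentina = 6724L, Australia = 3844L, Brazil = 13204L, Egypt = 4729L,
    Germany = 9506L, `Hong Kong` = 3012L, India = 12765L, Indonesia = 6992L,
    Israel = 3669L, Japan = 20543L, Kenya = 11389L, Mexico = 5776L,
    Nigeria = 6827L, Philippines = 5292L, Poland = 10389L,
    `South Africa` = 2651L, Spain = 6290L, Tanzania = 9075L,
    Turkiye = 1473L, `United Kingdom` = 5368L, `United States` = 38312L,
    Sweden = 15068L)
}

#' Published pooled-network centrality indices
#'
#' The published per-node expected influence and predictability (R2) of
#' the pooled cross-national flourishing network.
#'
#' @return A tibble with columns `code`, `label`, `expected_influence`,
#'   `predictability`, in the canonical item order.
#' @export
flourish_reported_centrality <- function() {
  items <- sfm_items()
  ei <- c(H = 1.019, LS = 1.010, MH = 0.931, PH = 0.689, SP = 0.831,
          W = 0.948, PG = 0.783, GU = 0.535, C = 0.951, SR = 0.904,
          E = 0.805, WS = 0.746)
  r2 <- c(H = 0.515, LS = 0.523, MH = 0.406, PH = 0.298, SP = 0.352,
          W = 0.454, PG = 0.300, GU = 0.197, C = 0.512, SR = 0.507,
          E = 0.478, WS = 0.471)
  tibble::tibble(
    code = items$code,
    label = items$label,
    expected_influence = unname(ei[items$code]),
    predictability = unname(r2[items$code])
  )
}

#' Published model-comparison fit statistics
#'
#' Chi-square statistics and degrees of freedom of the first-order CFA and
#' bi-factor measurement models as published for the pooled total sample
#' (N = 202,898), used for closed-form fit-index arithmetic.
#'
#' @return A tibble with columns `model`, `chisq`, `df`, `n`.
#' @export
flourish_reported_fit <- function() {
  tibble::tibble(
    model = c("cfa6", "bifactor", "second_order_g"),
    chisq = c(21058.84, 35153.39, 35343.95),
    df = c(39L, 42L, 48L),
    n = 202898L
  )
}
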