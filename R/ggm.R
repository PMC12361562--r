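# Gaussian graphical model core: maps between correlation, precision and
# partial-correlation representations, Gaussian discrepancy, fit indices,
# edge significance, centrality primitives.

.check_square <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  invisible(m)
}

.sym <- function(m) (m + t(m)) / 2

#' Partial correlations from a correlation matrix
#'
#' Standardizes the negative inverse of a correlation matrix: with
#' K = R^-1, the partial correlation between i and j given all other
#' variables is -K_ij / sqrt(K_ii K_jj).
#'
#' @param R Symmetric positive-definite correlation matrix.
#' @return A symmetric hollow matrix of partial correlations (the edge
#'   weights of the Gaussian graphical model on `R`).
#' @seealso [corr_from_pcor()] for the inverse map.
#' @examples
#' pcor_from_corr(flourish_total_correlations())["E", "WS"]
#' @export
pcor_from_corr <- function(R) {
  .check_square(R, "R")
  R <- .sym(R)
  K <- tryCatch(chol2inv(chol(R)), error = function(e) {
    stop(sprintf(
      "correlation matrix is not positive definite (reciprocal condition number %.3g)",
      rcond(R)
    ), call. = FALSE)
  })
  d <- sqrt(diag(K))
  omega <- -K / tcrossprod(d)
  diag(omega) <- 0
  dimnames(omega) <- dimnames(R)
  .sym(omega)
}

#' Correlation matrix implied by a partial-correlation network
#'
#' Inverse of [pcor_from_corr()]: reconstructs the unique correlation
#' matrix whose Gaussian graphical model has the given edge weights, by
#' standardizing the inverse of I - omega.
#'
#' @param omega Symmetric hollow matrix of partial correlations; I - omega
#'   must be positive definite.
#' @return A correlation matrix (unit diagonal, positive definite).
#' @export
corr_from_pcor <- function(omega) {
  .check_square(omega, "omega")
  if (any(abs(diag(omega)) > 1e-8)) {
    stop("`omega` must have a zero diagonal", call. = FALSE)
  }
  A <- diag(nrow(omega)) - .sym(omega)
  diag(A) <- 1
  B <- tryCatch(chol2inv(chol(A)), error = function(e) {
    stop("I - omega is not positive definite; no valid correlation matrix is implied",
         call. = FALSE)
  })
  R <- stats::cov2cor(B)
  dimnames(R) <- dimnames(omega)
  .sym(R)
}

#' Construct a partial-correlation network object
#'
#' @param omega Symmetric hollow matrix of partial correlations.
#' @param se Optional matrix of per-edge standard errors.
#' @param pvals Optional matrix of per-edge p-values.
#' @param nodes Node labels; defaults to `colnames(omega)`.
#' @return An object of class `ggm_network`: a list with elements `omega`,
#'   `omega_raw` (unthresholded copy), `se`, `pvals`, `retained` (logical
#'   edge mask) and `nodes`.
#' @export
ggm_network <- function(omega, se = NULL, pvals = NULL, nodes = colnames(omega)) {
  .check_square(omega, "omega")
  p <- nrow(omega)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  dimnames(omega) <- list(nodes, nodes)
  omega <- .sym(omega)
  diag(omega) <- 0
  if (any(abs(omega) >= 1)) stop("partial correlations must lie in (-1, 1)", call. = FALSE)
  retained <- matrix(TRUE, p, p, dimnames = dimnames(omega))
  diag(retained) <- FALSE
  structure(
    list(omega = omega, omega_raw = omega, se = se, pvals = pvals,
         retained = retained, nodes = nodes),
    class = "ggm_network"
  )
}

#' @export
print.ggm_network <- function(x, ...) {
  p <- length(x$nodes)
  kept <- sum(x$retained[upper.tri(x$retained)] & x$omega[upper.tri(x$omega)] != 0)
  cat(sprintf("<ggm_network> %d nodes, %d/%d nonzero retained edges\n",
              p, kept, choose(p, 2)))
  invisible(x)
}

#' Classical significance test for partial-correlation edges
#'
#' Two-sided t-test of each partial correlation controlling for the
#' k = p - 2 remaining variables: t = w * sqrt((n - 2 - k) / (1 - w^2))
#' on n - 2 - k degrees of freedom.
#'
#' @param omega Symmetric hollow partial-correlation matrix.
#' @param n Sample size; must exceed p + 2.
#' @return Matrix of two-sided p-values (diagonal = 1).
#' @export
edge_pvalues <- function(omega, n) {
  .check_square(omega, "omega")
  p <- nrow(omega)
  k <- p - 2
  if (n <= p + 2) stop("sample size too small for the partial-correlation test", call. = FALSE)
  df <- n - 2 - k
  if (any(abs(omega[upper.tri(omega)]) >= 1)) {
    warning("|partial correlation| = 1: p-value set to 0")
  }
  w <- pmin(pmax(omega, -1), 1)
  tstat <- w * sqrt(df / pmax(1 - w^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tstat), df = df)
  diag(pv) <- 1
  dimnames(pv) <- dimnames(omega)
  pv
}

#' Threshold a network at a significance level
#'
#' Sets edges whose p-value is at or above `alpha` to zero without
#' re-estimating the remaining edges; the unthresholded weights are kept
#' in `omega_raw`.
#'
#' @param network A `ggm_network` with `pvals` present.
#' @param alpha Edge retention level (default 0.05).
#' @return The network with updated `omega` and `retained` mask.
#' @export
threshold_network <- function(network, alpha = 0.05) {
  stopifnot(inherits(network, "ggm_network"))
  if (is.null(network$pvals)) stop("network has no edge p-values; run edge_pvalues() first", call. = FALSE)
  retained <- network$pvals < alpha
  diag(retained) <- FALSE
  network$retained <- retained
  omega <- network$omega_raw
  omega[!retained] <- 0
  diag(omega) <- 0
  network$omega <- .sym(omega)
  network$alpha <- alpha
  network
}

#' Gaussian maximum-likelihood discrepancy
#'
#' The ML fitting function for covariance structures,
#' F = log|Sigma| - log|S| + tr(S Sigma^-1) - p, together with the full
#' multivariate-normal log-likelihood (including the p*log(2*pi) constant,
#' so AIC/BIC are comparable across models) and the chi-square statistic
#' (n - 1) * F.
#'
#' @param S Observed covariance/correlation matrix (positive definite).
#' @param Sigma Model-implied matrix (positive definite).
#' @param n Sample size.
#' @return A list with elements `F`, `loglik`, `chisq`.
#' @export
gaussian_discrepancy <- function(S, Sigma, n) {
  .check_square(S, "S"); .check_square(Sigma, "Sigma")
  p <- nrow(S)
  cS <- tryCatch(chol(S), error = function(e) stop("S is not positive definite", call. = FALSE))
  cM <- tryCatch(chol(Sigma), error = function(e) stop("Sigma is not positive definite", call. = FALSE))
  ldS <- 2 * sum(log(diag(cS)))
  ldM <- 2 * sum(log(diag(cM)))
  tr <- sum(chol2inv(cM) * S)
  Fval <- ldM - ldS + tr - p
  loglik <- -(n / 2) * (p * log(2 * pi) + ldM + tr)
  list(F = Fval, loglik = loglik, chisq = (n - 1) * Fval)
}

#' Chi-square based fit indices and information criteria
#'
#' Computes NFI, RFI, TLI, CFI, RMSEA (with 90% CI), AIC and BIC from a
#' model chi-square and the independence-baseline chi-square. TLI and RFI
#' are `NA` when the model df is zero.
#'
#' @param chisq,df Model chi-square and degrees of freedom.
#' @param chisq_baseline,df_baseline Independence-model values.
#' @param n Sample size.
#' @param loglik Full Gaussian log-likelihood of the model.
#' @param n_params Number of free parameters.
#' @return A one-row tibble of class `fit_indices`.
#' @export
fit_indices <- function(chisq, df, chisq_baseline, df_baseline, n,
                        loglik = NA_real_, n_params = NA_real_) {
  stopifnot(df >= 0, df_baseline >= df)
  nfi <- (chisq_baseline - chisq) / chisq_baseline
  ratio_b <- chisq_baseline / df_baseline
  if (df > 0) {
    ratio_m <- chisq / df
    rfi <- 1 - ratio_m / ratio_b
    tli <- (ratio_b - ratio_m) / (ratio_b - 1)
    rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
    ci <- .rmsea_ci(chisq, df, n)
  } else {
    rfi <- NA_real_; tli <- NA_real_; rmsea <- 0
    ci <- c(0, 0)
  }
  cfi <- 1 - max(chisq - df, 0) / max(chisq_baseline - df_baseline, chisq - df, 0)
  out <- tibble::tibble(
    chisq = chisq, df = df,
    chisq_baseline = chisq_baseline, df_baseline = df_baseline,
    nfi = nfi, rfi = rfi, tli = tli, cfi = cfi,
    rmsea = rmsea, rmsea_lo = ci[1], rmsea_hi = ci[2],
    aic = -2 * loglik + 2 * n_params,
    bic = -2 * loglik + n_params * log(n),
    loglik = loglik, n_params = n_params, n = n
  )
  class(out) <- c("fit_indices", class(out))
  out
}

# 90% CI for RMSEA by inverting the noncentral chi-square distribution
.rmsea_ci <- function(chisq, df, n, level = 0.90) {
  lo_tail <- (1 + level) / 2
  hi_tail <- (1 - level) / 2
  root <- function(target) {
    f <- function(ncp) stats::pchisq(chisq, df, ncp = ncp) - target
    if (f(0) < 0) return(0)
    upper <- max(chisq * 2, df + 10)
    while (f(upper) > 0 && upper < 1e10) upper <- upper * 2
    stats::uniroot(f, c(0, upper))$root
  }
  lam_lo <- tryCatch(root(lo_tail), error = function(e) 0)
  lam_hi <- tryCatch(root(hi_tail), error = function(e) 0)
  sqrt(c(lam_lo, lam_hi) / (df * (n - 1)))
}

#' Expected influence of each node
#'
#' The signed sum of a node's edge weights: strong positive connections
#' raise expected influence, negative edges lower it.
#'
#' @param omega Symmetric hollow partial-correlation matrix, or a
#'   `ggm_network`.
#' @return Named numeric vector of per-node expected influence.
#' @export
expected_influence <- function(omega) {
  if (inherits(omega, "ggm_network")) omega <- omega$omega
  .check_square(omega, "omega")
  rowSums(omega)
}

#' Node predictability (network-implied R-squared)
#'
#' The proportion of each node's variance explained by all other nodes:
#' with K = R^-1, R2_i = 1 - 1 / K_ii, identical to the coefficient of
#' determination of the regression of node i on all remaining nodes.
#'
#' @param R Positive-definite correlation matrix.
#' @return Named numeric vector of per-node R-squared values in [0, 1).
#' @export
predictability <- function(R) {
  .check_square(R, "R")
  K <- chol2inv(chol(.sym(R)))
  r2 <- 1 - 1 / diag(K)
  names(r2) <- colnames(R)
  r2
}
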