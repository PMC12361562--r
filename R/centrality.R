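# Centrality tables for pooled and single-country networks, and the
# parametric-bootstrap test of pairwise centrality differences.

#' Centrality indices of a network
#'
#' Expected influence (signed row sum of edge weights) and predictability
#' (variance of each node explained by all others, computed from the
#' correlation matrix implied by the network) for every node.
#'
#' @param network A `ggm_network` or a symmetric hollow matrix of partial
#'   correlations, or a `magna_fit` (uses its pooled network).
#' @param label Network label carried in the output (e.g. a country code
#'   or `"pooled"`).
#' @param use_thresholded Use the thresholded edge weights (default) or
#'   the raw unthresholded ones for expected influence. Predictability is
#'   always computed from the unthresholded (saturated) structure: it is
#'   a variance-explained quantity of the estimated joint distribution,
#'   and zeroing edges for display can leave no admissible distribution.
#' @return A `centrality_table`: 12-row tibble with columns `node`,
#'   `expected_influence`, `predictability`, `network`; column means are
#'   attached as attribute `means`.
#' @export
centrality_table <- function(network, label = "pooled", use_thresholded = TRUE) {
  if (inherits(network, "magna_fit")) network <- network$network
  if (inherits(network, "ggm_network")) {
    omega <- if (use_thresholded) network$omega else network$omega_raw
    omega_r2 <- network$omega_raw
  } else {
    omega <- omega_r2 <- network
  }
  .check_square(omega, "network")
  ei <- expected_influence(omega)
  r2 <- predictability(corr_from_pcor(omega_r2))
  nodes <- colnames(omega)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(omega)))
  out <- tibble::tibble(node = nodes,
                        expected_influence = unname(ei),
                        predictability = unname(r2),
                        network = label)
  attr(out, "means") <- c(expected_influence = mean(ei), predictability = mean(r2))
  class(out) <- c("centrality_table", class(out))
  out
}

#' Parametric bootstrap test of pairwise centrality differences
#'
#' Draws `B` edge-weight vectors from a multivariate normal centered at
#' the pooled network's estimated edge weights with their delta-method
#' covariance, recomputes both centrality indices for every draw, and for
#' each node pair reports p = 2 * min(P(diff < 0), P(diff > 0)), capped
#' at 1. Zero proportions are reported as 2/B rather than 0 (the
#' resolution limit of the bootstrap). The default significance level is
#' the Bonferroni level for all pairwise comparisons (0.05/66 rounded to
#' 0.0008 for 12 nodes).
#'
#' @param fit A `magna_fit`.
#' @param B Number of bootstrap draws (the reference analysis uses 1e6;
#'   smaller B trades Monte-Carlo precision for time).
#' @param seed Integer seed.
#' @param alpha Significance level for the decision mask.
#' @param use_thresholded Center draws on thresholded (`TRUE`) or raw
#'   (`FALSE`, default) pooled edge weights.
#' @return A `centrality_difference` object: per-index p-value matrices,
#'   significance masks, `B`, `seed`, `alpha`.
#' @export
bootstrap_centrality_difference <- function(fit, B = 1e6, seed = 1,
                                            alpha = NULL, use_thresholded = FALSE) {
  stopifnot(inherits(fit, "magna_fit"), B >= 1000)
  net <- fit$network
  nodes <- net$nodes
  p <- length(nodes)
  if (is.null(alpha)) alpha <- bonferroni_alpha(p)
  w0 <- vech_offdiag(if (use_thresholded) net$omega else net$omega_raw)
  V <- .sym(fit$vcov_omega)
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    warning("edge-weight covariance not positive semidefinite; repaired by eigenvalue clipping")
  }
  ev$values <- pmax(ev$values, 0)
  L <- ev$vectors %*% diag(sqrt(ev$values))
  m <- length(w0)

  # map edge vector draws to node-sum (expected influence) via the pair
  # incidence matrix; predictability needs a per-draw matrix inversion
  pr <- pair_index(p)
  Minc <- matrix(0, p, m)
  Minc[cbind(pr[, 1], seq_len(m))] <- 1
  Minc[cbind(pr[, 2], seq_len(m))] <- 1

  chunk <- 5000L
  ei_gt <- ei_lt <- matrix(0, p, p)
  r2_gt <- r2_lt <- matrix(0, p, p)
  done <- 0
  rng <- .local_rng(seed)
  rng({
    while (done < B) {
      nb <- min(chunk, B - done)
      Z <- matrix(stats::rnorm(m * nb), m, nb)
      Wd <- w0 + L %*% Z                       # m x nb edge draws
      EI <- Minc %*% Wd                        # p x nb
      R2 <- matrix(NA_real_, p, nb)
      for (b in seq_len(nb)) {
        om <- unvech_offdiag(Wd[, b], nodes, diag_value = 0)
        A <- diag(p) - om
        Binv <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
        if (is.null(Binv)) next                # inadmissible draw: skipped
        K <- chol2inv(chol(stats::cov2cor(Binv)))
        R2[, b] <- 1 - 1 / diag(K)
      }
      ok <- !is.na(R2[1, ])
      for (i in 1:(p - 1)) for (j in (i + 1):p) {
        d_ei <- EI[i, ] - EI[j, ]
        ei_gt[i, j] <- ei_gt[i, j] + sum(d_ei > 0)
        ei_lt[i, j] <- ei_lt[i, j] + sum(d_ei < 0)
        d_r2 <- R2[i, ok] - R2[j, ok]
        r2_gt[i, j] <- r2_gt[i, j] + sum(d_r2 > 0)
        r2_lt[i, j] <- r2_lt[i, j] + sum(d_r2 < 0)
      }
      done <- done + nb
    }
  })
  finish <- function(gt, lt) {
    tot <- gt + lt
    pm <- matrix(1, p, p, dimnames = list(nodes, nodes))
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      if (tot[i, j] == 0) { pm[i, j] <- pm[j, i] <- 1; next }
      lo <- min(gt[i, j], lt[i, j]) / tot[i, j]
      pv <- min(2 * lo, 1)
      if (pv == 0) pv <- 2 / B                  # resolution floor
      pm[i, j] <- pm[j, i] <- pv
    }
    pm
  }
  p_ei <- finish(ei_gt, ei_lt)
  p_r2 <- finish(r2_gt, r2_lt)
  structure(
    list(p_expected_influence = p_ei, p_predictability = p_r2,
         sig_expected_influence = p_ei < alpha, sig_predictability = p_r2 < alpha,
         alpha = alpha, B = B, seed = seed, nodes = nodes),
    class = "centrality_difference"
  )
}

#' @export
print.centrality_difference <- function(x, ...) {
  cat(sprintf("<centrality_difference> %d draws, alpha = %g\n", x$B, x$alpha))
  np <- choose(length(x$nodes), 2)
  cat(sprintf("  significant pairs: expected influence %d/%d, predictability %d/%d\n",
              sum(x$sig_expected_influence[upper.tri(x$sig_expected_influence)]), np,
              sum(x$sig_predictability[upper.tri(x$sig_predictability)]), np))
  invisible(x)
}

#' Centrality tables for every single-country network
#'
#' Fits each country's saturated partial-correlation network, thresholds
#' it at `alpha`, and tabulates both centrality indices.
#'
#' @param cset A `correlation_set`.
#' @param alpha Edge retention level.
#' @return One `centrality_table` tibble with all countries stacked.
#' @export
single_country_centralities <- function(cset, alpha = 0.05) {
  stopifnot(inherits(cset, "correlation_set"))
  purrr::map_dfr(seq_len(nrow(cset)), function(i) {
    omega <- pcor_from_corr(cset$R[[i]])
    net <- ggm_network(omega)
    net$pvals <- edge_pvalues(omega, cset$n[i])
    net <- threshold_network(net, alpha)
    centrality_table(net, label = cset$country[i])
  })
}
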