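# broom-style tidiers for the fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a partial-correlation network into an edge list
#'
#' @param x A `ggm_network`.
#' @param ... Unused.
#' @return A tibble with one row per node pair: `from`, `to`, `weight`
#'   (thresholded), `weight_raw`, and `se`, `p`, `retained` when present.
#' @export
tidy.ggm_network <- function(x, ...) {
  p <- length(x$nodes)
  pr <- pair_index(p)
  tibble::tibble(
    from = x$nodes[pr[, 2]],
    to = x$nodes[pr[, 1]],
    weight = x$omega[lower.tri(x$omega)],
    weight_raw = x$omega_raw[lower.tri(x$omega_raw)],
    se = if (!is.null(x$se)) x$se[lower.tri(x$se)] else NA_real_,
    p = if (!is.null(x$pvals)) x$pvals[lower.tri(x$pvals)] else NA_real_,
    retained = x$retained[lower.tri(x$retained)]
  )
}

#' Tidy a MAGNA fit into its per-edge estimates
#'
#' @param x A `magna_fit`.
#' @param ... Unused.
#' @return The per-edge tibble: pooled edge weight with SE, 95% CI,
#'   p-value and retention flag, pooled marginal correlation `rho`, and
#'   random-effect SD `tau`.
#' @export
tidy.magna_fit <- function(x, ...) x$edges

#' One-row summary of a MAGNA fit
#'
#' @param x A `magna_fit`.
#' @param ... Unused.
#' @return A one-row tibble: country count, total N, retained edges,
#'   tau mean/range, convergence flag.
#' @export
glance.magna_fit <- function(x, ...) {
  tibble::tibble(
    n_countries = length(x$countries),
    n_total = sum(x$n),
    n_edges = nrow(x$edges),
    n_retained = sum(x$edges$retained),
    mean_tau = x$mean_tau, min_tau = x$min_tau, max_tau = x$max_tau,
    converged = x$convergence$converged
  )
}

#' Tidy a fitted measurement model's parameters
#'
#' @param x A `measurement_fit`.
#' @param ... Unused.
#' @return A tibble with `block`, `term`, `estimate` for every free
#'   parameter.
#' @export
tidy.measurement_fit <- function(x, ...) {
  b <- .split_theta(x$spec, x$theta)
  purrr::map_dfr(names(b), function(nm) {
    tibble::tibble(block = nm,
                   term = paste0(nm, seq_along(b[[nm]])),
                   estimate = b[[nm]])
  })
}

#' One-row fit summary of a measurement model
#'
#' @param x A `measurement_fit`.
#' @param ... Unused.
#' @return The model's [fit_indices()] row plus `model` and `converged`.
#' @export
glance.measurement_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model = x$spec$kind), x$indices,
                   tibble::tibble(converged = x$convergence$converged))
}

#' Tidy a heterogeneity comparison
#'
#' @param x A `heterogeneity_comparison`.
#' @param ... Unused.
#' @return Two-row tibble (single-country vs pooled) with loglik, k, AIC,
#'   BIC.
#' @export
tidy.heterogeneity_comparison <- function(x, ...) {
  tibble::tibble(
    model = c("single_country", "pooled"),
    loglik = c(x$loglik_single, x$loglik_pooled),
    n_params = c(x$k_single, x$k_pooled),
    aic = c(x$aic_single, x$aic_pooled),
    bic = c(x$bic_single, x$bic_pooled)
  )
}

#' Tidy a centrality difference test
#'
#' @param x A `centrality_difference`.
#' @param ... Unused.
#' @return A tibble with one row per node pair and index: `index`,
#'   `from`, `to`, `p`, `significant`.
#' @export
tidy.centrality_difference <- function(x, ...) {
  p <- length(x$nodes)
  pr <- pair_index(p)
  one <- function(pm, sm, nm) {
    tibble::tibble(index = nm,
                   from = x$nodes[pr[, 2]], to = x$nodes[pr[, 1]],
                   p = pm[lower.tri(pm)], significant = sm[lower.tri(sm)])
  }
  dplyr::bind_rows(
    one(x$p_expected_influence, x$sig_expected_influence, "expected_influence"),
    one(x$p_predictability, x$sig_predictability, "predictability")
  )
}
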