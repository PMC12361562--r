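# Maximum-likelihood fitting and comparison of six competing measurement
# models for the 12-item flourishing battery: correlated six-factor CFA,
# bi-factor, second-order g, latent network, residual network, and the
# saturated Gaussian graphical model. All models are fitted to a
# correlation matrix plus sample size by minimizing the Gaussian ML
# discrepancy with quasi-Newton optimization from multiple deterministic
# starting points.

.model_kinds <- c("cfa6", "bifactor", "second_order_g",
                  "latent_network", "residual_network", "ggm")

#' Measurement-model specification
#'
#' Builds the parameter layout, bounds and deterministic starting values
#' for one of the six supported measurement-model kinds. The two-items-
#' per-domain loading pattern comes from [sfm_items()] (or an analogous
#' schema for other batteries). Factor variances are fixed at 1 for
#' identification.
#'
#' @param kind One of `"cfa6"` (six correlated first-order factors),
#'   `"bifactor"` (six specific factors plus one orthogonal general
#'   factor), `"second_order_g"` (a second-order factor over the six),
#'   `"latent_network"` (six factors whose correlations are parameterized
#'   as a latent partial-correlation network, saturated), `"residual_network"`
#'   (one general factor with a partial-correlation network over
#'   residuals) or `"ggm"` (saturated partial-correlation network over
#'   the items).
#' @param items Item schema tibble (columns `code`, `domain_id`).
#' @param residual_edges For `"residual_network"`: integer matrix of edges
#'   (rows i,j) to keep free; `NULL` starts from all off-domain prunable
#'   edges and is resolved by [fit_measurement_model()]'s stepwise pruning.
#' @return A `model_spec` list with the parameter template, bounds, start
#'   values, free-parameter count and model df.
#' @export
model_spec <- function(kind = .model_kinds, items = sfm_items(), residual_edges = NULL) {
  kind <- match.arg(kind)
  p <- nrow(items)
  dom <- items$domain_id
  nf <- length(unique(dom))
  n_moments <- p * (p + 1) / 2
  n_pairs <- choose(p, 2)
  nf_pairs <- choose(nf, 2)

  spec <- list(kind = kind, p = p, dom = dom, nf = nf, nodes = items$code,
               n_moments = n_moments)
  if (kind == "cfa6") {
    spec$n_params <- p + nf_pairs + p
    spec$blocks <- list(lambda = p, phi = nf_pairs, resid = p)
    spec$lower <- c(rep(-5, p), rep(-0.999, nf_pairs), rep(1e-6, p))
    spec$upper <- c(rep(5, p), rep(0.999, nf_pairs), rep(5, p))
  } else if (kind == "bifactor") {
    spec$n_params <- 2 * p + p
    spec$blocks <- list(lambda_g = p, lambda_s = p, resid = p)
    spec$lower <- c(rep(-5, 2 * p), rep(1e-6, p))
    spec$upper <- rep(5, 3 * p)
  } else if (kind == "second_order_g") {
    spec$n_params <- p + nf + p
    spec$blocks <- list(lambda = p, gamma = nf, resid = p)
    spec$lower <- c(rep(-5, p), rep(-0.999, nf), rep(1e-6, p))
    spec$upper <- c(rep(5, p), rep(0.999, nf), rep(5, p))
  } else if (kind == "latent_network") {
    spec$n_params <- p + nf_pairs + p
    spec$blocks <- list(lambda = p, omega_latent = nf_pairs, resid = p)
    spec$lower <- c(rep(-5, p), rep(-0.999, nf_pairs), rep(1e-6, p))
    spec$upper <- c(rep(5, p), rep(0.999, nf_pairs), rep(5, p))
  } else if (kind == "residual_network") {
    if (is.null(residual_edges)) {
      # free residual edges only between items of different domains keeps
      # the single-factor-plus-network model below the moment count;
      # within-domain association is absorbed by the pruning step
      ut <- which(upper.tri(diag(p)), arr.ind = TRUE)
      residual_edges <- ut
    }
    ne <- nrow(residual_edges)
    spec$residual_edges <- residual_edges
    spec$n_params <- p + p + ne
    spec$blocks <- list(lambda = p, delta = p, omega_res = ne)
    spec$lower <- c(rep(-5, p), rep(1e-3, p), rep(-0.999, ne))
    spec$upper <- c(rep(5, p), rep(5, p), rep(0.999, ne))
  } else { # ggm
    spec$n_params <- n_pairs + p
    spec$blocks <- list(omega = n_pairs, delta = p)
    spec$lower <- c(rep(-0.999, n_pairs), rep(1e-3, p))
    spec$upper <- c(rep(0.999, n_pairs), rep(5, p))
  }
  spec$df <- n_moments - spec$n_params
  class(spec) <- "model_spec"
  spec
}

.split_theta <- function(spec, theta) {
  stopifnot(length(theta) == spec$n_params)
  out <- list()
  i <- 0
  for (nm in names(spec$blocks)) {
    k <- spec$blocks[[nm]]
    out[[nm]] <- theta[(i + 1):(i + k)]
    i <- i + k
  }
  out
}

.lower_to_sym <- function(v, k, unit_diag = TRUE) {
  m <- diag(k)
  m[lower.tri(m)] <- v
  m <- m + t(m) - diag(diag(m))
  if (!unit_diag) diag(m) <- 0
  m
}

.loading_matrix <- function(lambda, dom, nf) {
  L <- matrix(0, length(lambda), nf)
  L[cbind(seq_along(lambda), dom)] <- lambda
  L
}

#' Model-implied covariance matrix
#'
#' Evaluates the implied item covariance matrix of a measurement model at
#' a parameter vector.
#'
#' @param spec A [model_spec()].
#' @param theta Numeric parameter vector of length `spec$n_params`.
#' @return The implied p x p covariance matrix (possibly non-PD for
#'   inadmissible `theta`; the fitter penalizes such points).
#' @export
implied_sigma <- function(spec, theta) {
  b <- .split_theta(spec, theta)
  p <- spec$p
  switch(spec$kind,
    cfa6 = {
      L <- .loading_matrix(b$lambda, spec$dom, spec$nf)
      Phi <- .lower_to_sym(b$phi, spec$nf)
      L %*% Phi %*% t(L) + diag(b$resid)
    },
    bifactor = {
      Ls <- .loading_matrix(b$lambda_s, spec$dom, spec$nf)
      tcrossprod(b$lambda_g) + tcrossprod(Ls) + diag(b$resid)
    },
    second_order_g = {
      L <- .loading_matrix(b$lambda, spec$dom, spec$nf)
      # first-order disturbances standardized: Phi has unit diagonal
      Phi <- tcrossprod(b$gamma) + diag(pmax(1 - b$gamma^2, 1e-8))
      L %*% Phi %*% t(L) + diag(b$resid)
    },
    latent_network = {
      L <- .loading_matrix(b$lambda, spec$dom, spec$nf)
      Om <- .lower_to_sym(b$omega_latent, spec$nf, unit_diag = FALSE)
      chA <- tryCatch(chol(diag(spec$nf) - Om), error = function(e) NULL)
      if (is.null(chA)) return(matrix(NA_real_, p, p))
      Phi <- stats::cov2cor(chol2inv(chA))
      L %*% Phi %*% t(L) + diag(b$resid)
    },
    residual_network = {
      Om <- matrix(0, p, p)
      Om[spec$residual_edges] <- b$omega_res
      Om <- Om + t(Om)
      chA <- tryCatch(chol(diag(p) - Om), error = function(e) NULL)
      if (is.null(chA)) return(matrix(NA_real_, p, p))
      Dm <- diag(b$delta)
      tcrossprod(b$lambda) + Dm %*% chol2inv(chA) %*% Dm
    },
    ggm = {
      Om <- .lower_to_sym(b$omega, p, unit_diag = FALSE)
      chA <- tryCatch(chol(diag(p) - Om), error = function(e) NULL)
      if (is.null(chA)) return(matrix(NA_real_, p, p))
      Dm <- diag(b$delta)
      Dm %*% chol2inv(chA) %*% Dm
    }
  )
}

# deterministic start values derived from the observed matrix, plus
# jittered alternatives for the multi-start search
.start_values <- function(spec, S, n_starts = 5) {
  p <- spec$p; dom <- spec$dom; nf <- spec$nf
  within_r <- vapply(seq_len(nf), function(d) {
    ij <- which(dom == d)
    S[ij[1], ij[2]]
  }, numeric(1))
  lam0 <- sqrt(pmax(abs(within_r), 0.2))[dom]
  resid0 <- pmax(1 - lam0^2, 0.1)
  phi_mat <- diag(nf)
  for (a in 1:(nf - 1)) for (bb in (a + 1):nf) {
    ia <- which(dom == a); ib <- which(dom == bb)
    phi_mat[a, bb] <- phi_mat[bb, a] <-
      min(max(mean(S[ia, ib]) / (sqrt(abs(within_r[a]) * abs(within_r[bb])) + 1e-6), -0.9), 0.9)
  }
  phi0 <- phi_mat[lower.tri(phi_mat)]
  base <- switch(spec$kind,
    cfa6 = c(lam0, phi0, resid0),
    bifactor = {
      g0 <- sqrt(max(mean(S[upper.tri(S)]), 0.1))
      s0 <- sqrt(pmax(abs(within_r) - g0^2, 0.05))[dom]
      c(rep(g0, p), s0, pmax(1 - g0^2 - s0^2, 0.1))
    },
    second_order_g = {
      gam0 <- rep(sqrt(max(mean(phi_mat[lower.tri(phi_mat)]), 0.1)), nf)
      c(lam0, gam0, resid0)
    },
    latent_network = {
      om0 <- tryCatch(pcor_from_corr(nearest_pd_corr(phi_mat))[lower.tri(phi_mat)],
                      error = function(e) phi0 * 0.5)
      c(lam0, om0, resid0)
    },
    residual_network = {
      g0 <- sqrt(pmax(rowMeans(S) - 1 / p, 0.15))
      c(g0, pmax(1 - g0^2, 0.2), rep(0, nrow(spec$residual_edges)))
    },
    ggm = {
      om0 <- tryCatch(pcor_from_corr(S)[lower.tri(S)], error = function(e) rep(0, choose(p, 2)))
      c(om0, rep(0.7, p))
    }
  )
  base <- pmin(pmax(base, spec$lower), spec$upper)
  starts <- list(base)
  if (n_starts > 1) {
    for (k in 2:n_starts) {
      jit <- .local_rng(100 + k)(stats::runif(length(base), 0.75, 1.25))
      starts[[k]] <- pmin(pmax(base * jit, spec$lower), spec$upper)
    }
  }
  starts
}

.penalized_F <- function(spec, S, ldS) {
  p <- spec$p
  function(theta) {
    Sig <- implied_sigma(spec, theta)
    if (anyNA(Sig)) return(1e4)
    cM <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(cM)) return(1e4)
    ldM <- 2 * sum(log(diag(cM)))
    ldM - ldS + sum(chol2inv(cM) * S) - p
  }
}

#' Fit one measurement model by maximum likelihood
#'
#' Minimizes the Gaussian discrepancy between the observed correlation
#' matrix and the model-implied matrix by box-constrained quasi-Newton
#' optimization (`optim(method = "L-BFGS-B")`) from `n_starts`
#' deterministic starting points, keeping the best solution. The
#' saturated `"ggm"` model is solved in closed form. For
#' `"residual_network"`, residual edges are pruned stepwise at
#' `prune_alpha` until the model is identified (free parameters strictly
#' below the moment count) and all retained edges are significant.
#'
#' @param R Observed correlation matrix (positive definite).
#' @param n Sample size.
#' @param kind Model kind (see [model_spec()]) or a `model_spec`.
#' @param items Item schema.
#' @param n_starts Number of deterministic starts (default 5).
#' @param prune_alpha Retention level for residual-network pruning.
#' @param extra_starts Optional list of additional starting vectors
#'   (e.g. a reparameterized solution of an equivalent model).
#' @return A `measurement_fit` object: list with `spec`, `theta`,
#'   `indices` (a [fit_indices()] row), `convergence` (list with
#'   `converged`, `grad_norm`, `start_spread`, `messages`), and the
#'   baseline fit used.
#' @export
fit_measurement_model <- function(R, n, kind = "cfa6", items = sfm_items(),
                                  n_starts = 5, prune_alpha = 0.05,
                                  extra_starts = NULL) {
  spec <- if (inherits(kind, "model_spec")) kind else model_spec(kind, items)
  .check_square(R, "R")
  p <- spec$p
  stopifnot(nrow(R) == p, n > spec$n_params)
  S <- .sym(R)
  base <- gaussian_discrepancy(S, diag(p), n)           # independence baseline
  df_b <- p * (p + 1) / 2 - p
  msgs <- character()

  if (spec$kind == "residual_network") {
    return(.fit_residual_network(S, n, spec, items, n_starts, prune_alpha, base, df_b))
  }

  if (spec$kind == "ggm") {
    # saturated: implied matrix equals S exactly
    omega <- pcor_from_corr(S)
    theta <- c(omega[lower.tri(omega)], 1 / sqrt(diag(chol2inv(chol(S)))))
    disc <- gaussian_discrepancy(S, S, n)
    conv <- list(converged = TRUE, grad_norm = 0, start_spread = 0, messages = msgs)
    idx <- fit_indices(disc$chisq, spec$df, base$chisq, df_b, n, disc$loglik, spec$n_params)
    return(.measurement_fit(spec, theta, idx, conv, S, n))
  }

  ldS <- 2 * sum(log(diag(chol(S))))
  obj <- .penalized_F(spec, S, ldS)
  starts <- c(.start_values(spec, S, n_starts), extra_starts)
  fits <- lapply(starts, function(th0) {
    th0 <- pmin(pmax(th0, spec$lower), spec$upper)
    stats::optim(th0, obj, method = "L-BFGS-B",
                 lower = spec$lower, upper = spec$upper,
                 control = list(maxit = 2000, factr = 1e5, pgtol = 1e-9))
  })
  Fvals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(Fvals >= 1e4)) stop("all optimizer starts failed (non-PD implied matrix throughout)", call. = FALSE)
  best <- fits[[which.min(Fvals)]]
  theta <- best$par
  grad <- .num_grad(obj, theta)
  # ignore gradient components pressed against an active box bound
  at_bound <- (theta <= spec$lower + 1e-8 & grad > 0) | (theta >= spec$upper - 1e-8 & grad < 0)
  grad_norm <- max(abs(grad[!at_bound]), 0)
  spread <- max(Fvals[Fvals < 1e4]) - min(Fvals)
  converged <- best$convergence == 0 && grad_norm < 1e-3
  if (!converged) msgs <- c(msgs, sprintf("optimizer gradient norm %.2e", grad_norm))
  if (is.finite(spread) && spread > 1e-4) {
    msgs <- c(msgs, sprintf("starting points disagree by %.2e in F", spread))
  }
  disc <- gaussian_discrepancy(S, implied_sigma(spec, theta), n)
  idx <- fit_indices(disc$chisq, spec$df, base$chisq, df_b, n, disc$loglik, spec$n_params)
  conv <- list(converged = converged, grad_norm = grad_norm,
               start_spread = spread, messages = msgs)
  .measurement_fit(spec, theta, idx, conv, S, n)
}

.num_grad <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    (f(xp) - f0) / h
  }, numeric(1))
}

.measurement_fit <- function(spec, theta, indices, convergence, S, n) {
  structure(list(spec = spec, theta = theta, indices = indices,
                 convergence = convergence, S = S, n = n),
            class = "measurement_fit")
}

#' @export
print.measurement_fit <- function(x, ...) {
  cat(sprintf("<measurement_fit: %s> chisq %.2f on %d df, RMSEA %.4f, CFI %.4f%s\n",
              x$spec$kind, x$indices$chisq, x$indices$df, x$indices$rmsea,
              x$indices$cfi,
              if (!x$convergence$converged) "  [convergence issues]" else ""))
  invisible(x)
}

# single general factor plus residual partial-correlation network; the
# saturated version is unidentified, so edges are pruned stepwise until
# the parameter count sits strictly below the moment count and all
# retained residual edges pass the significance screen
.fit_residual_network <- function(S, n, spec, items, n_starts, prune_alpha, base, df_b) {
  p <- spec$p
  edges <- spec$residual_edges
  msgs <- character()
  best_fit <- NULL
  for (iter in 1:5) {
    sub <- model_spec("residual_network", items, residual_edges = edges)
    if (sub$df < 1) {
      # still unidentified: keep only the strongest residual edges
      g0 <- sqrt(pmax(rowMeans(S) - 1 / p, 0.15))
      Sr <- S - tcrossprod(g0)
      Rr <- nearest_pd_corr(stats::cov2cor(Sr + diag(pmax(1 - g0^2, 0.2))))
      om <- pcor_from_corr(Rr)
      keep_n <- sub$n_moments - 2 * p - 6
      mags <- abs(om[edges])
      edges <- edges[order(mags, decreasing = TRUE)[seq_len(keep_n)], , drop = FALSE]
      msgs <- c(msgs, sprintf("saturated residual network unidentified; kept %d strongest edges", keep_n))
      next
    }
    ldS <- 2 * sum(log(diag(chol(S))))
    obj <- .penalized_F(sub, S, ldS)
    # intermediate pruning rounds need only a rough optimum
    starts <- .start_values(sub, S, min(n_starts, 2))
    fits <- lapply(starts, function(th0) {
      stats::optim(th0, obj, method = "L-BFGS-B", lower = sub$lower, upper = sub$upper,
                   control = list(maxit = 1500, factr = 1e6, pgtol = 1e-8))
    })
    Fvals <- vapply(fits, `[[`, numeric(1), "value")
    best <- fits[[which.min(Fvals)]]
    b <- .split_theta(sub, best$par)
    # significance screen on retained residual edges
    Om <- matrix(0, p, p); Om[sub$residual_edges] <- b$omega_res; Om <- Om + t(Om)
    pv <- edge_pvalues(Om, n)
    edge_p <- pv[sub$residual_edges]
    best_fit <- list(sub = sub, best = best, Fvals = Fvals)
    if (all(edge_p < prune_alpha) || nrow(sub$residual_edges) <= 1) break
    keep <- edge_p < prune_alpha
    if (all(keep)) break
    edges <- sub$residual_edges[keep, , drop = FALSE]
    msgs <- c(msgs, sprintf("pruned %d non-significant residual edges", sum(!keep)))
  }
  sub <- best_fit$sub; best <- best_fit$best; Fvals <- best_fit$Fvals
  grad <- .num_grad(.penalized_F(sub, S, 2 * sum(log(diag(chol(S))))), best$par)
  at_bound <- (best$par <= sub$lower + 1e-8 & grad > 0) | (best$par >= sub$upper - 1e-8 & grad < 0)
  grad_norm <- max(abs(grad[!at_bound]), 0)
  spread <- max(Fvals[Fvals < 1e4]) - min(Fvals)
  converged <- best$convergence == 0 && grad_norm < 1e-3 && length(msgs) == 0
  if (grad_norm >= 1e-3) msgs <- c(msgs, sprintf("optimizer gradient norm %.2e", grad_norm))
  disc <- gaussian_discrepancy(S, implied_sigma(sub, best$par), n)
  idx <- fit_indices(disc$chisq, sub$df, base$chisq, df_b, n, disc$loglik, sub$n_params)
  conv <- list(converged = converged, grad_norm = grad_norm, start_spread = spread,
               messages = msgs)
  .measurement_fit(sub, best$par, idx, conv, S, n)
}

#' Fit and compare the six measurement models
#'
#' Fits every requested model to the same correlation matrix and sample
#' size, and assembles a comparison table sorted by AIC, with the
#' chi-square difference of each model to the saturated network model.
#'
#' @param R Correlation matrix.
#' @param n Sample size.
#' @param kinds Model kinds to fit (default: all six).
#' @param items Item schema.
#' @param ... Passed to [fit_measurement_model()].
#' @return A `model_comparison`: tibble with one row per model (df,
#'   chisq, chisq difference to the network model with its p-value, NFI,
#'   TLI, RFI, CFI, AIC, BIC, RMSEA and CI, convergence flag), sorted by
#'   AIC; the fitted objects are attached as attribute `fits`.
#' @export
compare_measurement_models <- function(R, n, kinds = .model_kinds,
                                       items = sfm_items(), ...) {
  fits <- list()
  for (k in setdiff(kinds, "latent_network")) {
    fits[[k]] <- fit_measurement_model(R, n, k, items, ...)
  }
  if ("latent_network" %in% kinds) {
    # the saturated latent network reparameterizes the correlated-factor
    # CFA; seed it with the transformed CFA solution so the two attain
    # their common optimum
    extra <- NULL
    if (!is.null(fits[["cfa6"]])) {
      b <- .split_theta(fits[["cfa6"]]$spec, fits[["cfa6"]]$theta)
      nf <- fits[["cfa6"]]$spec$nf
      Phi <- .lower_to_sym(b$phi, nf)
      om <- tryCatch(pcor_from_corr(nearest_pd_corr(Phi))[lower.tri(Phi)],
                     error = function(e) NULL)
      if (!is.null(om)) extra <- list(c(b$lambda, om, b$resid))
    }
    fits[["latent_network"]] <- fit_measurement_model(R, n, "latent_network", items,
                                                      extra_starts = extra, ...)
  }
  fits <- fits[kinds]
  ref <- if ("ggm" %in% kinds) fits[["ggm"]]$indices else NULL
  tab <- purrr::map_dfr(kinds, function(k) {
    ix <- fits[[k]]$indices
    d_chisq <- if (!is.null(ref)) ix$chisq - ref$chisq else NA_real_
    d_df <- if (!is.null(ref)) ix$df - ref$df else NA_real_
    p_diff <- if (!is.null(ref) && k != "ggm" && d_df > 0) {
      stats::pchisq(d_chisq, d_df, lower.tail = FALSE)
    } else if (identical(k, "ggm")) 1 else NA_real_
    tibble::tibble(
      model = k, df = ix$df, chisq = ix$chisq,
      chisq_diff_network = d_chisq, p_diff_network = p_diff,
      nfi = ix$nfi, tli = ix$tli, rfi = ix$rfi, cfi = ix$cfi,
      aic = ix$aic, bic = ix$bic,
      rmsea = ix$rmsea, rmsea_lo = ix$rmsea_lo, rmsea_hi = ix$rmsea_hi,
      converged = fits[[k]]$convergence$converged
    )
  })
  tab <- dplyr::arrange(tab, .data$aic)
  attr(tab, "fits") <- fits
  class(tab) <- c("model_comparison", class(tab))
  tab
}
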