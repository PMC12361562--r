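# Random-effects meta-analytic Gaussian network aggregation (MAGNA):
# heterogeneity testing across country correlation matrices and pooling
# of correlation structures into one network with per-edge random-effect
# SDs, standard errors and confidence intervals.
#
# Estimation uses a two-stage marginal formulation: each country
# contributes its vector of 66 sample correlations y_c with analytic
# (Isserlis / Pearson-Filon) sampling covariance V_c = V(rho) / n_c, and
# y_c ~ N(rho, V_c + diag(tau^2)). For fixed tau the fixed effects have a
# closed-form GLS solution, so the likelihood is profiled and maximized
# over tau alone with an analytic gradient.

#' Half-vectorize the off-diagonal of a symmetric matrix
#'
#' Extracts the lower triangle in column-major order (the canonical edge
#' order used throughout the package); `unvech_offdiag()` is the inverse,
#' rebuilding a symmetric matrix with unit diagonal.
#'
#' @param R Symmetric matrix.
#' @return Named vector of length p(p-1)/2 (names like `"H-LS"`).
#' @export
vech_offdiag <- function(R) {
  .check_square(R, "R")
  v <- R[lower.tri(R)]
  names(v) <- pair_names(colnames(R), nrow(R))
  v
}

#' @rdname vech_offdiag
#' @param y Off-diagonal vector in lower-triangle column-major order.
#' @param nodes Node labels.
#' @param diag_value Diagonal fill (1 for correlation, 0 for networks).
#' @export
unvech_offdiag <- function(y, nodes = NULL, diag_value = 1) {
  p <- (1 + sqrt(1 + 8 * length(y))) / 2
  if (abs(p - round(p)) > 1e-8) stop("length of `y` is not p(p-1)/2 for integer p", call. = FALSE)
  p <- as.integer(round(p))
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- y
  m <- m + t(m)
  diag(m) <- diag_value
  if (!is.null(nodes)) dimnames(m) <- list(nodes, nodes)
  m
}

pair_names <- function(nodes, p) {
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  idx <- which(lower.tri(diag(p)), arr.ind = TRUE)
  paste0(nodes[idx[, 2]], "-", nodes[idx[, 1]])
}

pair_index <- function(p) which(lower.tri(diag(p)), arr.ind = TRUE)[, 2:1, drop = FALSE]

#' Asymptotic covariance of sample correlations
#'
#' The Isserlis / Pearson--Filon expression for the large-sample
#' covariance of two Pearson correlations r_ij and r_kl computed on the
#' same multivariate-normal sample, evaluated at a correlation matrix and
#' divided by the sample size.
#'
#' @param R Correlation matrix at which to evaluate the covariance.
#' @param n Sample size.
#' @return A symmetric positive-semidefinite matrix of dimension
#'   p(p-1)/2, in the [vech_offdiag()] edge order.
#' @export
corr_sampling_cov <- function(R, n) {
  .check_square(R, "R")
  stopifnot(n >= 1)
  p <- nrow(R)
  pr <- pair_index(p)
  m <- nrow(pr)
  V <- matrix(0, m, m)
  for (a in seq_len(m)) {
    i <- pr[a, 1]; j <- pr[a, 2]
    for (b in a:m) {
      k <- pr[b, 1]; l <- pr[b, 2]
      v <- 0.5 * R[i, j] * R[k, l] *
             (R[i, k]^2 + R[i, l]^2 + R[j, k]^2 + R[j, l]^2) +
           R[i, k] * R[j, l] + R[i, l] * R[j, k] -
           R[i, j] * (R[j, k] * R[j, l] + R[i, k] * R[i, l]) -
           R[k, l] * (R[i, k] * R[j, k] + R[i, l] * R[j, l])
      V[a, b] <- V[b, a] <- v
    }
  }
  dimnames(V) <- list(pair_names(colnames(R), p), pair_names(colnames(R), p))
  V / n
}

#' Heterogeneity test: single-country versus pooled saturated models
#'
#' Compares, by AIC and BIC, a model in which every country keeps its own
#' saturated correlation structure against a model in which one common
#' structure is constrained to hold in all countries (the ML common
#' structure is the sample-size-weighted average matrix). A preference
#' for the single-country model indicates cross-country heterogeneity
#' beyond sampling variation.
#'
#' @param cset A `correlation_set` with at least 2 countries.
#' @return A `heterogeneity_comparison` list: per-model log-likelihood,
#'   parameter counts, AIC, BIC, the pooled chi-square, and the preferred
#'   model under each criterion.
#' @export
fit_saturated_models <- function(cset) {
  stopifnot(inherits(cset, "correlation_set"))
  C <- nrow(cset)
  if (C < 2) stop("heterogeneity comparison needs at least 2 countries", call. = FALSE)
  p <- nrow(cset$R[[1]])
  n_pairs <- choose(p, 2)
  Rbar <- Reduce(`+`, purrr::map2(cset$R, cset$n, `*`)) / sum(cset$n)
  ll_single <- ll_pooled <- chisq_pooled <- 0
  for (i in seq_len(C)) {
    ll_single <- ll_single + gaussian_discrepancy(cset$R[[i]], cset$R[[i]], cset$n[i])$loglik
    dp <- gaussian_discrepancy(cset$R[[i]], Rbar, cset$n[i])
    ll_pooled <- ll_pooled + dp$loglik
    chisq_pooled <- chisq_pooled + dp$chisq
  }
  # scale convention: p free variances per country in both models
  k_single <- C * (n_pairs + p)
  k_pooled <- n_pairs + C * p
  N <- sum(cset$n)
  out <- list(
    loglik_single = ll_single, loglik_pooled = ll_pooled,
    k_single = k_single, k_pooled = k_pooled,
    chisq_pooled = chisq_pooled, df_pooled = (C - 1) * n_pairs,
    aic_single = -2 * ll_single + 2 * k_single,
    bic_single = -2 * ll_single + k_single * log(N),
    aic_pooled = -2 * ll_pooled + 2 * k_pooled,
    bic_pooled = -2 * ll_pooled + k_pooled * log(N),
    n_countries = C, n_total = N
  )
  out$preferred_aic <- if (out$aic_single < out$aic_pooled) "single" else "pooled"
  out$preferred_bic <- if (out$bic_single < out$bic_pooled) "single" else "pooled"
  class(out) <- "heterogeneity_comparison"
  out
}

#' @export
print.heterogeneity_comparison <- function(x, ...) {
  cat(sprintf("<heterogeneity_comparison> %d countries, N = %d\n", x$n_countries, x$n_total))
  cat(sprintf("  single-country saturated: AIC %.2f  BIC %.2f\n", x$aic_single, x$bic_single))
  cat(sprintf("  pooled saturated:         AIC %.2f  BIC %.2f\n", x$aic_pooled, x$bic_pooled))
  cat(sprintf("  preferred: AIC -> %s, BIC -> %s\n", x$preferred_aic, x$preferred_bic))
  invisible(x)
}

# profile negative log-likelihood machinery ---------------------------------

.magna_profile <- function(tau, ylist, Vlist) {
  m <- length(tau)
  T2 <- tau^2
  Ws <- lapply(Vlist, function(V) {
    Sig <- V
    diag(Sig) <- diag(Sig) + T2
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(W = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
  })
  if (any(vapply(Ws, is.null, logical(1)))) return(NULL)
  A <- matrix(0, m, m)
  bvec <- numeric(m)
  for (i in seq_along(ylist)) {
    A <- A + Ws[[i]]$W
    bvec <- bvec + Ws[[i]]$W %*% ylist[[i]]
  }
  rho <- drop(solve(A, bvec))
  nll <- 0
  grad <- numeric(m)
  for (i in seq_along(ylist)) {
    r <- ylist[[i]] - rho
    Wr <- Ws[[i]]$W %*% r
    nll <- nll + 0.5 * (Ws[[i]]$logdet + sum(r * Wr))
    grad <- grad + tau * (diag(Ws[[i]]$W) - drop(Wr)^2)
  }
  list(nll = nll, grad = grad, rho = rho, A = A)
}

#' Random-effects meta-analytic Gaussian network aggregation
#'
#' Pools per-country correlation matrices into a common cross-country
#' network. Each country's vector of sample correlations is modelled as
#' multivariate normal around pooled fixed-effect correlations, with
#' covariance equal to its analytic sampling covariance plus a diagonal
#' matrix of per-edge between-country variances tau^2. Fixed effects are
#' profiled out in closed form (GLS) and the likelihood is maximized over
#' tau by box-constrained quasi-Newton iteration with an analytic
#' gradient; the sampling covariances are re-evaluated at the pooled
#' estimate and the fit repeated until the pooled correlations settle.
#'
#' The pooled correlations are then re-expressed as a partial-correlation
#' network; edge standard errors follow by the delta method through the
#' correlation-to-partial-correlation map, giving per-edge 95% confidence
#' intervals and two-sided normal p-values, thresholded at `alpha`.
#'
#' @param cset A `correlation_set` (at least 3 countries for an
#'   identifiable tau, unless `fix_tau` is supplied).
#' @param alpha Edge retention level for thresholding (default 0.05).
#' @param fix_tau Optional fixed value (scalar or per-edge) for the
#'   random-effect SDs; `fix_tau = 0` reduces the model to fixed-effects
#'   pooling.
#' @param fisher_z Estimate on the Fisher-z scale instead of the raw
#'   correlation scale (variance-stabilized alternative; default FALSE,
#'   matching pooling of raw sample correlations).
#' @param max_outer Outer re-evaluations of the sampling covariance.
#' @return A `magna_fit` object: pooled correlations `rho` with
#'   covariance `vcov_rho`, random-effect SDs `tau` (with mean/min/max),
#'   the pooled `ggm_network` (SEs, p-values, thresholded mask), the
#'   delta-method covariance `vcov_omega` of the edge weights, per-edge
#'   CI table `edges`, and a convergence report.
#' @export
fit_magna <- function(cset, alpha = 0.05, fix_tau = NULL, fisher_z = FALSE,
                      max_outer = 3) {
  stopifnot(inherits(cset, "correlation_set"))
  C <- nrow(cset)
  if (C < 3 && is.null(fix_tau)) {
    stop("random-effect SDs are not identifiable with fewer than 3 countries; supply `fix_tau`",
         call. = FALSE)
  }
  p <- nrow(cset$R[[1]])
  nodes <- colnames(cset$R[[1]])
  m <- choose(p, 2)
  yraw <- purrr::map(cset$R, vech_offdiag)
  ybar <- drop(Reduce(`+`, purrr::map2(yraw, cset$n, `*`)) / sum(cset$n))
  rho <- ybar
  tau_fixed <- if (!is.null(fix_tau)) rep_len(fix_tau, m) else NULL

  to_z <- function(y) atanh(pmin(pmax(y, -0.999), 0.999))
  conv <- list(converged = TRUE, messages = character(), outer = 0)
  for (outer in seq_len(max_outer)) {
    Rpool <- nearest_pd_corr(unvech_offdiag(rho, nodes))
    V0 <- corr_sampling_cov(Rpool, 1)
    if (fisher_z) {
      d <- 1 / (1 - pmin(vech_offdiag(Rpool)^2, 0.998))
      V0 <- V0 * tcrossprod(d)
      ylist <- purrr::map(yraw, to_z)
    } else {
      ylist <- yraw
    }
    Vlist <- purrr::map(cset$n, function(nn) V0 / nn)

    if (!is.null(tau_fixed)) {
      prof <- .magna_profile(tau_fixed, ylist, Vlist)
      if (is.null(prof)) stop("covariance not positive definite at fixed tau", call. = FALSE)
      tau_hat <- tau_fixed
    } else {
      # moment start: between-country SD minus average sampling variance
      ymat <- do.call(cbind, ylist)
      v_between <- apply(ymat, 1, stats::var)
      v_sampling <- Reduce(`+`, purrr::map(Vlist, diag)) / C
      tau0 <- sqrt(pmax(v_between - v_sampling, 0))
      cache <- new.env(parent = emptyenv())
      profile_at <- function(tt) {
        key <- paste(signif(tt, 12), collapse = ",")
        if (identical(cache$key, key)) return(cache$val)
        val <- .magna_profile(tt, ylist, Vlist)
        cache$key <- key; cache$val <- val
        val
      }
      op <- stats::optim(
        tau0,
        fn = function(tt) {
          pr <- profile_at(tt)
          if (is.null(pr)) return(1e10)
          pr$nll
        },
        gr = function(tt) {
          pr <- profile_at(tt)
          if (is.null(pr)) return(rep(0, m))
          pr$grad
        },
        method = "L-BFGS-B", lower = rep(0, m), upper = rep(1, m),
        control = list(maxit = 500, factr = 1e5)
      )
      if (op$convergence != 0) {
        conv$converged <- FALSE
        conv$messages <- c(conv$messages, sprintf("tau optimizer: %s", op$message))
      }
      tau_hat <- op$par
      prof <- .magna_profile(tau_hat, ylist, Vlist)
      if (is.null(prof)) stop("likelihood evaluation failed at the optimum; optimizer trace: ",
                              paste(op$message, collapse = " "), call. = FALSE)
    }
    rho_new <- if (fisher_z) tanh(prof$rho) else prof$rho
    delta <- max(abs(rho_new - rho))
    rho <- rho_new
    conv$outer <- outer
    if (delta < 1e-7 && outer > 1) break
  }
  if (!is.null(tau_fixed)) tau_hat <- tau_fixed
  if (is.null(tau_fixed) && any(tau_hat < 1e-6)) {
    conv$messages <- c(conv$messages,
                       sprintf("%d random-effect SDs at the zero boundary", sum(tau_hat < 1e-6)))
  }

  vcov_rho <- solve(prof$A)
  if (fisher_z) {
    dz <- 1 - rho^2  # d tanh(z)/dz at the estimate
    vcov_rho <- vcov_rho * tcrossprod(dz)
  }
  Rhat <- unvech_offdiag(rho, nodes)
  pd <- nearest_pd_corr(Rhat)
  if (attr(pd, "proj_dist") > 1e-10) {
    conv$messages <- c(conv$messages, "pooled correlation matrix projected to positive definite")
    Rhat <- pd
    rho <- vech_offdiag(Rhat)
  }
  attr(Rhat, "proj_dist") <- NULL

  omega <- pcor_from_corr(Rhat)
  J <- .pcor_jacobian(Rhat)
  vcov_omega <- .sym(J %*% vcov_rho %*% t(J))
  se <- sqrt(pmax(diag(vcov_omega), 0))
  w <- vech_offdiag(omega)
  z <- ifelse(se > 0, w / se, Inf * sign(w))
  pvals_vec <- 2 * stats::pnorm(-abs(z))
  net <- ggm_network(omega,
                     se = unvech_offdiag(se, nodes, diag_value = 0),
                     pvals = unvech_offdiag(pvals_vec, nodes, diag_value = 1),
                     nodes = nodes)
  net <- threshold_network(net, alpha)

  edges <- tibble::tibble(
    edge = names(w),
    weight = unname(w),
    se = unname(se),
    ci_low = unname(w - 1.96 * se),
    ci_high = unname(w + 1.96 * se),
    p = unname(pvals_vec),
    retained = unname(pvals_vec < alpha),
    rho = unname(rho),
    tau = unname(tau_hat)
  )
  names(rho) <- names(w); names(tau_hat) <- names(w)
  structure(
    list(rho = rho, tau = tau_hat, vcov_rho = vcov_rho,
         pooled_corr = Rhat, network = net, vcov_omega = vcov_omega,
         edges = edges, alpha = alpha,
         mean_tau = mean(tau_hat), min_tau = min(tau_hat), max_tau = max(tau_hat),
         countries = cset$country, n = cset$n,
         fisher_z = fisher_z, fixed_tau = !is.null(tau_fixed),
         convergence = conv),
    class = "magna_fit"
  )
}

# numeric Jacobian of the correlation -> partial-correlation map,
# d vech(omega) / d vech(R), used for delta-method edge SEs
.pcor_jacobian <- function(R, h = 1e-6) {
  p <- nrow(R)
  y0 <- vech_offdiag(R)
  m <- length(y0)
  f <- function(y) vech_offdiag(pcor_from_corr(unvech_offdiag(y, colnames(R))))
  J <- matrix(0, m, m)
  for (k in seq_len(m)) {
    yp <- y0; yp[k] <- yp[k] + h
    ym <- y0; ym[k] <- ym[k] - h
    J[, k] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

#' @export
print.magna_fit <- function(x, ...) {
  cat(sprintf("<magna_fit> %d countries, N = %d\n", length(x$countries), sum(x$n)))
  cat(sprintf("  retained edges: %d / %d at alpha = %g\n",
              sum(x$edges$retained), nrow(x$edges), x$alpha))
  cat(sprintf("  random-effect SD: mean %.3f, range [%.3f, %.3f]\n",
              x$mean_tau, x$min_tau, x$max_tau))
  if (!x$convergence$converged || length(x$convergence$messages)) {
    cat("  notes:", paste(x$convergence$messages, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Per-edge random-effect SD summary
#'
#' @param fit A `magna_fit`.
#' @return A tibble of the per-edge random-effect SDs sorted descending,
#'   with attributes `mean`, `min`, `max`.
#' @export
random_effect_summary <- function(fit) {
  stopifnot(inherits(fit, "magna_fit"))
  out <- tibble::tibble(edge = names(fit$tau), tau = unname(fit$tau))
  out <- dplyr::arrange(out, dplyr::desc(.data$tau))
  attr(out, "mean") <- fit$mean_tau
  attr(out, "min") <- fit$min_tau
  attr(out, "max") <- fit$max_tau
  out
}

#' Export a pooled MAGNA network as an edge-list CSV
#'
#' @param fit A `magna_fit`.
#' @param path Output file.
#' @return The edge tibble, invisibly.
#' @export
write_magna_edges <- function(fit, path) {
  stopifnot(inherits(fit, "magna_fit"))
  readr::write_csv(fit$edges, path)
  invisible(fit$edges)
}
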