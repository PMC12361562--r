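# Multi-country synthetic data generator with known ground truth:
# a common partial-correlation network, per-edge random effects on the
# marginal-correlation scale, survey-style weights and MCAR missingness.

#' Project a symmetric matrix to the nearest positive-definite correlation matrix
#'
#' Clips eigenvalues at a small floor and rescales to unit diagonal.
#' Idempotent on matrices that are already positive definite with unit
#' diagonal.
#'
#' @param m Symmetric matrix.
#' @param floor Eigenvalue floor (default 1e-6).
#' @return A positive-definite correlation matrix; attribute `proj_dist`
#'   records the Frobenius distance moved.
#' @export
nearest_pd_corr <- function(m, floor = 1e-6) {
  m <- .sym(m)
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) > floor && max(abs(diag(m) - 1)) < 1e-12) {
    attr(m, "proj_dist") <- 0
    return(m)
  }
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- stats::cov2cor(out)
  dimnames(out) <- dimnames(m)
  out <- .sym(out)
  attr(out, "proj_dist") <- sqrt(sum((out - m)^2))
  out
}

#' Ground-truth pooled partial-correlation network
#'
#' Builds the pooled network that anchors a synthetic multi-country study.
#' `"reported"` returns the published pooled cross-national flourishing
#' network; `"zero"` an empty network; `"random"` a sparse random network
#' with the requested edge density, shrunk toward zero until the implied
#' correlation matrix is positive definite.
#'
#' @param source One of `"reported"`, `"zero"`, `"random"`.
#' @param p Node count (ignored for `"reported"`, which is 12-node).
#' @param density Fraction of nonzero edges for `"random"`.
#' @param seed Integer seed for `"random"`.
#' @param max_weight Magnitude cap for random edge draws.
#' @return Symmetric hollow matrix of partial correlations whose implied
#'   correlation matrix is positive definite.
#' @export
pooled_truth <- function(source = c("reported", "zero", "random"),
                         p = 12, density = 0.3, seed = 1, max_weight = 0.4) {
  source <- match.arg(source)
  stopifnot(p >= 3)
  if (source == "reported") return(flourish_pooled_edges())
  nodes <- if (p == 12) sfm_item_codes() else paste0("V", seq_len(p))
  omega <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (source == "zero") return(omega)
  stopifnot(density > 0, density <= 1)
  n_pairs <- choose(p, 2)
  n_edges <- max(1L, round(density * n_pairs))
  draws <- .local_rng(seed)({
    list(idx = sample.int(n_pairs, n_edges),
         w = stats::runif(n_edges, -max_weight, max_weight))
  })
  idx <- draws$idx
  w <- draws$w
  ut <- which(upper.tri(omega))
  for (attempt in 1:20) {
    omega[] <- 0
    omega[ut[idx]] <- w
    omega <- omega + t(omega)
    ok <- tryCatch({
      corr_from_pcor(omega); TRUE
    }, error = function(e) FALSE)
    if (ok) return(omega)
    w <- w * 0.8  # shrink toward zero and retry
  }
  stop("could not build a positive-definite random network; lower `density` or `max_weight`",
       call. = FALSE)
}

# evaluate `expr` under a temporary seed without disturbing the global RNG
.local_rng <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
  }
}

#' Country-level correlation structures around a pooled network
#'
#' Adds independent Gaussian random effects with per-edge standard
#' deviation `tau` to the pooled *marginal* correlations (heterogeneity in
#' the study design is expressed on the unconditional-association scale),
#' then projects each perturbed matrix to the nearest positive-definite
#' correlation matrix.
#'
#' @param pooled_partials Pooled partial-correlation matrix (the network
#'   scale); its implied marginal correlations are perturbed.
#' @param tau Scalar or length-choose(p,2) vector of nonnegative
#'   random-effect SDs on the marginal-correlation scale.
#' @param n_countries Number of country structures to draw.
#' @param seed Integer seed.
#' @return List of positive-definite correlation matrices; attribute
#'   `proj_dist` holds the per-country projection distances.
#' @export
perturb_country_structures <- function(pooled_partials, tau, n_countries, seed = 1) {
  p <- nrow(pooled_partials)
  n_pairs <- choose(p, 2)
  if (length(tau) == 1) tau <- rep(tau, n_pairs)
  stopifnot(length(tau) == n_pairs, all(tau >= 0), n_countries >= 1)
  R0 <- corr_from_pcor(pooled_partials)
  y0 <- vech_offdiag(R0)
  rng <- .local_rng(seed)
  noise <- rng(matrix(stats::rnorm(n_pairs * n_countries, sd = tau),
                      nrow = n_pairs, ncol = n_countries))
  dist <- numeric(n_countries)
  out <- vector("list", n_countries)
  for (cc in seq_len(n_countries)) {
    y <- pmin(pmax(y0 + noise[, cc], -0.99), 0.99)
    R <- unvech_offdiag(y, nodes = colnames(R0))
    R <- nearest_pd_corr(R)
    dist[cc] <- attr(R, "proj_dist")
    attr(R, "proj_dist") <- NULL
    out[[cc]] <- R
  }
  if (mean(dist > 1e-10) > 0.5) {
    warning("more than half of the drawn structures required positive-definite projection; `tau` may be too large")
  }
  attr(out, "proj_dist") <- dist
  out
}

#' Configuration table for synthetic country samples
#'
#' Default study conditions: the 22 published country sample sizes,
#' per-country missingness drawn uniformly in the observed 0.1--1.7%
#' range, and log-normal sample weights with dispersion 0.5 (a typical
#' coefficient of variation for post-stratification survey weights).
#'
#' @param countries Character vector of country codes.
#' @param n Integer vector of respondent counts.
#' @param missing_rate Per-country missing-cell fraction in [0, 0.05];
#'   `NULL` draws each uniformly from [0.001, 0.017].
#' @param weight_dispersion Nonnegative log-scale SD of the weights.
#' @param seed Integer seed used for drawing missing rates.
#' @return A tibble with columns `country`, `n`, `missing_rate`,
#'   `weight_dispersion`, `seed` (per-country child seed).
#' @export
country_configs <- function(countries = names(flourish_country_sizes()),
                            n = unname(flourish_country_sizes()),
                            missing_rate = NULL,
                            weight_dispersion = 0.5,
                            seed = 1) {
  stopifnot(length(countries) == length(n), all(n >= 50))
  rng <- .local_rng(seed)
  if (is.null(missing_rate)) {
    missing_rate <- rng(stats::runif(length(n), 0.001, 0.017))
  }
  missing_rate <- rep_len(missing_rate, length(n))
  stopifnot(all(missing_rate >= 0), all(missing_rate <= 0.05))
  tibble::tibble(
    country = countries,
    n = as.integer(n),
    missing_rate = missing_rate,
    weight_dispersion = rep_len(weight_dispersion, length(n)),
    seed = seed + seq_along(n)
  )
}

#' Draw one country's respondent table
#'
#' Samples `n` rows from a multivariate normal with the given correlation
#' matrix, affine-maps items to mean 5, SD 2 (optionally clipping to the
#' 0--10 response range and rounding to integer responses), injects
#' missing cells completely at random, and attaches log-normal sample
#' weights normalized to mean 1.
#'
#' @param corr Positive-definite correlation matrix (items in columns).
#' @param config One row of [country_configs()] (list or one-row data frame).
#' @param clip Clip item scores to the response range (default `FALSE`:
#'   clipping distorts correlations and is off for inferential work).
#' @param discretize Round items to integers 0--10 (implies `clip`).
#' @return A tibble with columns `country`, `weight` and one column per
#'   item.
#' @export
generate_country_data <- function(corr, config, clip = FALSE, discretize = FALSE) {
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`corr` must be positive definite", call. = FALSE)
  config <- as.list(config)
  n <- config$n
  rng <- .local_rng(config$seed)
  out <- rng({
    x <- MASS::mvrnorm(n, mu = rep(0, ncol(corr)), Sigma = corr)
    x <- 5 + 2 * x
    if (discretize) clip <- TRUE
    if (clip) x <- pmin(pmax(x, sfm_response_range[1]), sfm_response_range[2])
    if (discretize) x <- round(x)
    if (config$missing_rate > 0) {
      miss <- stats::runif(length(x)) < config$missing_rate
      x[miss] <- NA_real_
    }
    w <- if (config$weight_dispersion > 0) {
      wr <- stats::rlnorm(n, meanlog = 0, sdlog = config$weight_dispersion)
      wr / mean(wr)
    } else rep(1, n)
    list(x = x, w = w)
  })
  colnames(out$x) <- colnames(corr)
  dplyr::bind_cols(
    tibble::tibble(country = config$country, weight = out$w),
    tibble::as_tibble(out$x)
  )
}

#' Simulate a complete multi-country study with known ground truth
#'
#' The one-call generator behind all recovery experiments: builds (or
#' accepts) a pooled network, draws per-country correlation structures
#' around it with random-effect SD `tau`, and generates each country's
#' respondent table with weights and missingness.
#'
#' @param configs Country configuration tibble from [country_configs()].
#' @param pooled Pooled partial-correlation matrix (default: the published
#'   cross-national flourishing network).
#' @param tau Scalar or per-edge vector of marginal-scale random-effect
#'   SDs (default 0.12, the average cross-country heterogeneity of the
#'   flourishing network).
#' @param seed Integer master seed; all randomness fans out from it.
#' @param ... Passed to [generate_country_data()].
#' @return An object of class `synthetic_study`: list with `data` (one
#'   tibble of all respondents), `truth` (pooled network, tau,
#'   per-country true correlation matrices, seed) and `configs`.
#' @export
simulate_study <- function(configs = country_configs(seed = seed),
                           pooled = pooled_truth("reported"),
                           tau = 0.12, seed = 1, ...) {
  configs$seed <- seed * 1000L + seq_len(nrow(configs))
  country_corrs <- perturb_country_structures(
    pooled, tau, n_countries = nrow(configs), seed = seed * 1000L
  )
  names(country_corrs) <- configs$country
  data <- purrr::map_dfr(seq_len(nrow(configs)), function(i) {
    generate_country_data(country_corrs[[i]], configs[i, ], ...)
  })
  n_pairs <- choose(nrow(pooled), 2)
  structure(
    list(
      data = data,
      truth = list(
        pooled_partials = pooled,
        pooled_marginals = corr_from_pcor(pooled),
        tau = rep_len(tau, n_pairs),
        country_corrs = country_corrs,
        seed = seed
      ),
      configs = configs
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d countries, %d respondents, mean tau %.3f, seed %d\n",
              nrow(x$configs), nrow(x$data), mean(x$truth$tau), x$truth$seed))
  invisible(x)
}

#' Write a synthetic study to disk as plain text
#'
#' One respondent CSV per country (missing cells empty), the ground truth
#' as JSON, and one true correlation-matrix CSV per country.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cc in study$configs$country) {
    slug <- gsub("[^A-Za-z0-9]+", "_", cc)
    readr::write_csv(dplyr::filter(study$data, .data$country == cc),
                     file.path(dir, paste0("sample_", slug, ".csv")), na = "")
    rmat <- study$truth$country_corrs[[cc]]
    utils::write.csv(as.data.frame(rmat),
                     file.path(dir, paste0("truth_corr_", slug, ".csv")))
  }
  truth <- list(
    pooled_partials = study$truth$pooled_partials,
    tau = study$truth$tau,
    seed = study$truth$seed,
    countries = study$configs$country
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(dir)
}
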