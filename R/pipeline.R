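# End-to-end orchestration: simulate (or load) -> weighted correlations ->
# measurement-model comparison -> heterogeneity test -> random-effects
# MAGNA -> centrality -> bootstrap difference tests, with all artifacts
# written to disk and a machine-readable summary returned.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis in one validated list.
#' All randomness downstream fans out deterministically from `seed`.
#'
#' @param input_dir Directory with per-country respondent CSVs (columns
#'   `country, weight, <items>`); `NULL` simulates instead.
#' @param simulate List of arguments for [simulate_study()] (used when
#'   `input_dir` is `NULL`).
#' @param alpha_edge Edge retention level (default 0.05).
#' @param alpha_bonferroni Pairwise-comparison level; `NULL` computes
#'   0.05 / (number of node pairs) rounded to 4 decimals.
#' @param bootstrap_B Parametric-bootstrap draws (>= 1000).
#' @param seed Master seed.
#' @param kish,fisher_z,prune_refit,discretize Optional flags: Kish
#'   effective sample sizes, Fisher-z MAGNA estimation, prune-and-refit
#'   thresholding, integer 0--10 item responses.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = list(),
                            alpha_edge = 0.05, alpha_bonferroni = NULL,
                            bootstrap_B = 10000, seed = 1,
                            kish = FALSE, fisher_z = FALSE,
                            prune_refit = FALSE, discretize = FALSE) {
  stopifnot(alpha_edge > 0, alpha_edge < 1, bootstrap_B >= 1000)
  if (!is.null(alpha_bonferroni)) stopifnot(alpha_bonferroni > 0, alpha_bonferroni < 1)
  structure(list(input_dir = input_dir, simulate = simulate,
                 alpha_edge = alpha_edge, alpha_bonferroni = alpha_bonferroni,
                 bootstrap_B = bootstrap_B, seed = seed, kish = kish,
                 fisher_z = fisher_z, prune_refit = prune_refit,
                 discretize = discretize),
            class = "pipeline_config")
}

#' Run the full cross-national network pipeline
#'
#' Executes, in order: data acquisition (simulation or CSV input),
#' per-country listwise deletion and weighted correlation, pooled
#' measurement-model comparison, single-versus-pooled heterogeneity test,
#' random-effects MAGNA, centrality tables, and the parametric-bootstrap
#' centrality difference test. Each stage logs its inputs and outcomes;
#' any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for CSV/JSON artifacts; `NULL` skips
#'   writing.
#' @param quiet Suppress progress messages.
#' @return A named list (`study`, `correlations`, `model_comparison`,
#'   `heterogeneity`, `magna`, `centrality`, `centrality_single`,
#'   `difference_test`, `summary`); `summary` is the JSON-serializable
#'   digest written to `summary.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  res <- list()

  res$study <- stage("data", {
    if (is.null(config$input_dir)) {
      args <- config$simulate
      args$seed <- args$seed %||% config$seed
      if (config$discretize) args$discretize <- TRUE
      say("simulating study (seed %d)", args$seed)
      do.call(simulate_study, args)
    } else {
      say("reading respondent CSVs from %s", config$input_dir)
      files <- list.files(config$input_dir, pattern = "^sample_.*\\.csv$", full.names = TRUE)
      if (!length(files)) stop("no sample_*.csv files found", call. = FALSE)
      purrr::map_dfr(files, function(f) readr::read_csv(f, show_col_types = FALSE))
    }
  })

  res$correlations <- stage("weighted_correlation", {
    cs <- build_correlation_set(res$study, kish = config$kish)
    say("correlation set: %d countries, %d complete respondents, %d rows dropped",
        nrow(cs), round(sum(cs$n)), sum(cs$n_dropped))
    cs
  })
  cset <- res$correlations

  res$model_comparison <- stage("measurement_models", {
    Rbar <- Reduce(`+`, purrr::map2(cset$R, cset$n, `*`)) / sum(cset$n)
    say("comparing 6 measurement models on the pooled matrix (N = %d)", round(sum(cset$n)))
    compare_measurement_models(Rbar, sum(cset$n))
  })

  res$heterogeneity <- stage("heterogeneity", {
    if (nrow(cset) < 2) {
      say("single group: heterogeneity comparison skipped")
      NULL
    } else fit_saturated_models(cset)
  })

  res$magna <- stage("magna", {
    if (nrow(cset) < 3) {
      say("fewer than 3 groups: MAGNA reduces to fixed-effects pooling (tau = 0)")
      fit_magna(cset, alpha = config$alpha_edge, fix_tau = 0, fisher_z = config$fisher_z)
    } else {
      fit_magna(cset, alpha = config$alpha_edge, fisher_z = config$fisher_z)
    }
  })

  res$centrality <- stage("centrality", centrality_table(res$magna))
  res$centrality_single <- stage("centrality_single",
                                 single_country_centralities(cset, config$alpha_edge))

  res$difference_test <- stage("bootstrap", {
    alpha <- config$alpha_bonferroni %||% bonferroni_alpha(length(res$magna$network$nodes))
    say("parametric bootstrap: B = %d, alpha = %g", config$bootstrap_B, alpha)
    bootstrap_centrality_difference(res$magna, B = config$bootstrap_B,
                                    seed = config$seed, alpha = alpha)
  })

  res$summary <- list(
    seed = config$seed,
    countries = cset$country,
    n = cset$n,
    n_dropped = cset$n_dropped,
    model_comparison = as.data.frame(res$model_comparison),
    heterogeneity = if (!is.null(res$heterogeneity)) {
      res$heterogeneity[c("aic_single", "bic_single", "aic_pooled", "bic_pooled",
                          "preferred_aic", "preferred_bic")]
    },
    pooled_edges = as.data.frame(res$magna$edges),
    tau_summary = list(mean = res$magna$mean_tau, min = res$magna$min_tau,
                       max = res$magna$max_tau),
    centrality = as.data.frame(res$centrality),
    magna_convergence = res$magna$convergence[c("converged", "messages")],
    bootstrap = list(B = res$difference_test$B, alpha = res$difference_test$alpha,
                     n_significant_ei = sum(res$difference_test$sig_expected_influence) / 2,
                     n_significant_r2 = sum(res$difference_test$sig_predictability) / 2)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_correlation_set(cset, file.path(out_dir, "correlations"))
    readr::write_csv(res$model_comparison, file.path(out_dir, "model_comparison.csv"))
    write_magna_edges(res$magna, file.path(out_dir, "pooled_edges.csv"))
    readr::write_csv(res$centrality, file.path(out_dir, "centrality_pooled.csv"))
    readr::write_csv(res$centrality_single, file.path(out_dir, "centrality_single.csv"))
    utils::write.csv(res$difference_test$p_expected_influence,
                     file.path(out_dir, "pvals_expected_influence.csv"))
    utils::write.csv(res$difference_test$p_predictability,
                     file.path(out_dir, "pvals_predictability.csv"))
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
    say("artifacts written to %s", out_dir)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
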