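# Sample-weighted correlation estimation with listwise deletion: turns
# raw respondent tables into the per-country correlation matrices the
# network models consume.

#' Listwise deletion over the flourishing items
#'
#' Drops every row with a missing value on any of the 12 items; other
#' columns are ignored for the completeness check.
#'
#' @param data Respondent tibble containing the item columns.
#' @param items Item columns to check (default: the SFM codes).
#' @param min_rows Minimum complete rows required (default 50).
#' @return The complete-case tibble, with attribute `n_dropped` giving the
#'   number of removed rows.
#' @export
listwise_complete <- function(data, items = sfm_item_codes(), min_rows = 50) {
  missing_cols <- setdiff(items, names(data))
  if (length(missing_cols)) {
    stop("missing item columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(data[items])
  out <- data[keep, , drop = FALSE]
  if (nrow(out) < min_rows) {
    who <- if ("country" %in% names(data)) paste(unique(data$country), collapse = ", ") else "sample"
    stop(sprintf("fewer than %d complete rows after listwise deletion (%s)", min_rows, who),
         call. = FALSE)
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Sample-weighted Pearson correlation matrix
#'
#' Weighted correlations with weights normalized internally to mean 1;
#' with equal weights this reduces exactly to the unweighted Pearson
#' matrix. Requires complete data (run [listwise_complete()] first).
#'
#' @param data Complete-case respondent tibble.
#' @param items Item columns to correlate.
#' @param weight_col Name of the weight column; `NULL` for equal weights.
#' @param kish Use the Kish effective sample size (sum w)^2 / sum(w^2)
#'   instead of the nominal complete-case count for the attached `n`.
#' @return A correlation matrix with attribute `n` (the effective sample
#'   size convention chosen).
#' @export
weighted_correlation_matrix <- function(data, items = sfm_item_codes(),
                                        weight_col = "weight", kish = FALSE) {
  x <- as.matrix(data[items])
  if (anyNA(x)) stop("data contain missing values; run listwise_complete() first", call. = FALSE)
  w <- if (!is.null(weight_col) && weight_col %in% names(data)) data[[weight_col]] else rep(1, nrow(x))
  if (any(w < 0) || sum(w) <= 0) stop("weights must be nonnegative and not all zero", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero variance in item(s): ", paste(items[sds == 0], collapse = ", "), call. = FALSE)
  }
  cw <- stats::cov.wt(x, wt = w / sum(w), cor = TRUE, method = "unbiased")
  R <- .sym(cw$cor)
  diag(R) <- 1
  attr(R, "n") <- if (kish) sum(w)^2 / sum(w^2) else nrow(x)
  R
}

#' Build a correlation set from a multi-country respondent table
#'
#' Applies listwise deletion and weighted correlation estimation per
#' country, preserving the input country order.
#'
#' @param data Respondent tibble with a `country` column, a `weight`
#'   column and the 12 item columns; or a `synthetic_study`.
#' @param items Item columns.
#' @param kish Passed to [weighted_correlation_matrix()].
#' @return A `correlation_set`: tibble with columns `country`, `n`
#'   (post-deletion size), `n_dropped` and `R` (list column of weighted
#'   correlation matrices).
#' @export
build_correlation_set <- function(data, items = sfm_item_codes(), kish = FALSE) {
  if (inherits(data, "synthetic_study")) data <- data$data
  stopifnot("country" %in% names(data))
  countries <- unique(data$country)
  if (anyDuplicated(countries)) stop("duplicate country codes", call. = FALSE)
  rows <- purrr::map(countries, function(cc) {
    sub <- data[data$country == cc, , drop = FALSE]
    sub <- tryCatch(listwise_complete(sub, items),
                    error = function(e) stop(sprintf("[%s] %s", cc, conditionMessage(e)), call. = FALSE))
    R <- tryCatch(weighted_correlation_matrix(sub, items, kish = kish),
                  error = function(e) stop(sprintf("[%s] %s", cc, conditionMessage(e)), call. = FALSE))
    tibble::tibble(country = cc, n = attr(R, "n"),
                   n_dropped = attr(sub, "n_dropped"), R = list(.strip_n(R)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("correlation_set", class(out))
  out
}

.strip_n <- function(R) { attr(R, "n") <- NULL; R }

#' Assemble a correlation set from precomputed matrices
#'
#' @param R List of correlation matrices (12x12, unit diagonal).
#' @param n Vector of sample sizes, one per matrix.
#' @param countries Country labels.
#' @return A `correlation_set` tibble.
#' @export
correlation_set <- function(R, n, countries = names(R)) {
  if (is.null(countries)) countries <- paste0("G", seq_along(R))
  stopifnot(length(R) == length(n), length(countries) == length(R))
  for (m in R) {
    .check_square(m, "R[[i]]")
    stopifnot(max(abs(diag(m) - 1)) < 1e-8, max(abs(m - t(m))) < 1e-8)
  }
  out <- tibble::tibble(country = countries, n = as.numeric(n),
                        n_dropped = NA_integer_, R = unname(R))
  class(out) <- c("correlation_set", class(out))
  out
}

#' Write / read a correlation set as labeled CSV files plus a manifest
#'
#' Each matrix is written as a 12x12 labeled CSV; `manifest.csv` records
#' country order and sample sizes. The round trip is lossless to full
#' double precision.
#'
#' @param cset A `correlation_set`.
#' @param dir Directory to write to / read from.
#' @return `write_correlation_set()` returns `dir` invisibly;
#'   `read_correlation_set()` returns a `correlation_set`.
#' @export
write_correlation_set <- function(cset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cset))) {
    slug <- gsub("[^A-Za-z0-9]+", "_", cset$country[i])
    utils::write.csv(format(as.data.frame(cset$R[[i]]), digits = 17),
                     file.path(dir, paste0("corr_", slug, ".csv")))
  }
  utils::write.csv(
    data.frame(country = cset$country, n = cset$n,
               file = paste0("corr_", gsub("[^A-Za-z0-9]+", "_", cset$country), ".csv")),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_correlation_set
#' @param items Expected item-code headers.
#' @export
read_correlation_set <- function(dir, items = sfm_item_codes()) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"), check.names = FALSE)
  on_disk <- list.files(dir, pattern = "^corr_.*\\.csv$")
  orphans <- setdiff(on_disk, manifest$file)
  if (length(orphans)) {
    stop("correlation files on disk missing from the manifest: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  R <- purrr::map(seq_len(nrow(manifest)), function(i) {
    path <- file.path(dir, manifest$file[i])
    if (!file.exists(path)) {
      stop(sprintf("manifest lists '%s' but the file is absent", manifest$file[i]), call. = FALSE)
    }
    m <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(m)
    bad <- c(setdiff(items, colnames(m)), setdiff(colnames(m), items))
    if (length(bad)) {
      stop("item-code mismatch in ", manifest$file[i], ": ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
    m[items, items]
  })
  correlation_set(R, manifest$n, countries = manifest$country)
}
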