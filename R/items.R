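#' The Secure Flourish Measure item schema
#'
#' The 12 items of the Secure Flourish Measure (SFM), a self-report
#' flourishing instrument answered on 0--10 scales. Each of six flourishing
#' domains is measured by exactly two items; the fixed item order defined
#' here is used throughout the package (network node order, edge-vector
#' order, CSV column order).
#'
#' @return A tibble with one row per item and columns `code` (short item
#'   identifier), `label` (item content), `domain` (one of the six
#'   flourishing domains) and `domain_id` (integer 1--6).
#' @examples
#' sfm_items()
#' @export
sfm_items <- function() {
  tibble::tibble(
    code = c("H", "LS", "MH", "PH", "SP", "W",
             "PG", "GU", "C", "SR", "E", "WS"),
    label = c(
      "Happiness", "Life satisfaction",
      "Mental health", "Physical health",
      "Sense of purpose", "Life worthwhile",
      "Promote good", "Give up happiness",
      "Content with relationships", "Satisfying relationships",
      "Worry about expenses", "Worry about safety"
    ),
    domain = rep(c(
      "Happiness & life satisfaction",
      "Mental & physical health",
      "Meaning & purpose",
      "Character & virtue",
      "Close social relationships",
      "Financial & material stability"
    ), each = 2),
    domain_id = rep(1:6, each = 2)
  )
}

#' @rdname sfm_items
#' @export
sfm_item_codes <- function() sfm_items()$code

# response scale for the 11-point items
sfm_response_range <- c(0, 10)

#' Bonferroni level for all pairwise node comparisons
#'
#' Family-wise alpha divided by the number of unordered node pairs,
#' rounded to 4 decimals (the reporting convention used for the
#' centrality difference tests): for 12 nodes, 0.05 / 66 = 0.0008.
#'
#' @param p Number of nodes.
#' @param alpha Family-wise significance level.
#' @return A single numeric significance level.
#' @examples
#' bonferroni_alpha(12)
#' @export
bonferroni_alpha <- function(p = 12, alpha = 0.05) {
  stopifnot(p >= 2, alpha > 0, alpha < 1)
  round(alpha / choose(p, 2), 4)
}
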