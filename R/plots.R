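# ggplot2 graphics for networks, centrality and bootstrap results

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a partial-correlation network as an edge-weight matrix
#'
#' Heat-style lower-triangle display of the (thresholded) edge weights;
#' positive edges blue, negative red.
#'
#' @param object A `ggm_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ggm_network <- function(object, ...) {
  edges <- tidy(object)
  ggplot2::ggplot(edges, ggplot2::aes(x = factor(.data$to, levels = object$nodes),
                                      y = factor(.data$from, levels = rev(object$nodes)),
                                      fill = .data$weight)) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                                  limits = c(-1, 1) * max(abs(edges$weight), 0.1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "partial\ncorrelation") +
    ggplot2::theme_minimal()
}

#' Pooled edge weights with 95% confidence intervals
#'
#' The MAGNA analogue of a forest plot: every edge's pooled partial
#' correlation with its delta-method 95% CI, sorted by weight.
#'
#' @param object A `magna_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.magna_fit <- function(object, ...) {
  ed <- dplyr::arrange(object$edges, .data$weight)
  ed$edge <- factor(ed$edge, levels = ed$edge)
  ggplot2::ggplot(ed, ggplot2::aes(x = .data$weight, y = .data$edge, color = .data$retained)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "black", `FALSE` = "grey65")) +
    ggplot2::labs(x = "pooled edge weight (partial correlation)", y = NULL,
                  color = sprintf("p < %g", object$alpha)) +
    ggplot2::theme_minimal(base_size = 8)
}

#' Centrality profile plot
#'
#' Expected influence and predictability per node, one line per network
#' label (pooled and/or countries).
#'
#' @param tab A `centrality_table` (possibly several stacked).
#' @return A ggplot object.
#' @export
plot_centrality <- function(tab) {
  long <- tidyr::pivot_longer(tab, c("expected_influence", "predictability"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$node,
                                     group = .data$network, color = .data$network)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(orientation = "y", alpha = 0.5) +
    ggplot2::facet_wrap(~index, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Significance grid of pairwise centrality differences
#'
#' @param object A `centrality_difference`.
#' @param index `"expected_influence"` or `"predictability"`.
#' @param ... Unused.
#' @return A ggplot object: black cells mark pairs whose centrality
#'   differs at the Bonferroni level.
#' @export
autoplot.centrality_difference <- function(object, index = c("expected_influence", "predictability"), ...) {
  index <- match.arg(index)
  d <- dplyr::filter(tidy(object), .data$index == !!index)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$to, levels = object$nodes),
                                  y = factor(.data$from, levels = rev(object$nodes)),
                                  fill = .data$significant)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = sprintf("p < %g", object$alpha),
                  title = index) +
    ggplot2::theme_minimal()
}
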