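#' Heatmap of edge-wise F statistics with significant components marked
#'
#' @param object An `nbs_result`.
#' @param alpha Family-wise significance level for highlighting (default
#'   0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nbs_result
#' @export
autoplot.nbs_result <- function(object, alpha = 0.05, ...) {
  es <- object$edge_stats
  sig <- tidy(object)
  sig <- sig[sig$p_fwe < alpha, ]
  es$significant <- paste(es$node_a, es$node_b) %in% paste(sig$node_a, sig$node_b)
  ggplot2::ggplot(es, ggplot2::aes(x = node_a, y = node_b, fill = F_stat)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = es[es$significant, , drop = FALSE],
                       fill = NA, colour = "red", linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("Edge-wise F (%s weighting)", object$weighting),
                  subtitle = sprintf("red: component p_fwe < %s", alpha),
                  x = NULL, y = NULL, fill = "F") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-node degree centrality by group
#'
#' Grouped bars of mean degree centrality (strength) per node, one panel
#' per requested weighting - the standard display for spotting hub nodes
#' and their group-wise disruption.
#'
#' @param metrics Tibble from [compute_metrics()].
#' @param weightings Weightings to show (default: all present).
#' @return A ggplot object.
#' @export
plot_degree_centrality <- function(metrics, weightings = NULL) {
  df <- metrics %>%
    filter(scope == "nodal", metric == "degree_centrality")
  if (!is.null(weightings)) df <- filter(df, weighting %in% weightings)
  df <- df %>%
    group_by(node, group, weighting) %>%
    summarise(mean_value = mean(value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = node, y = mean_value, fill = group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~weighting, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean degree centrality", fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Group distributions of a global property
#'
#' @param metrics Tibble from [compute_metrics()].
#' @param which_metric Global metric name (e.g. `"global_efficiency"`).
#' @return A ggplot object (boxplots per group, one panel per weighting).
#' @export
plot_global_metric <- function(metrics, which_metric = "global_efficiency") {
  df <- filter(metrics, scope == "global", metric == which_metric)
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = value, fill = group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~weighting, scales = "free_y") +
    ggplot2::labs(x = NULL, y = which_metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
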