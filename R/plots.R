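# ggplot2 visualizations of the result objects.

#' PCA score plot coloured by group
#'
#' @param object a `morph_pca` object.
#' @param components two component names to plot (default PC1 vs PC2).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot morph_pca
#' @export
autoplot.morph_pca <- function(object, components = c("PC1", "PC2"), ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[components[1]]],
                                   y = .data[[components[2]]],
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::stat_ellipse(level = 0.95) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", components[1],
                  100 * object$ev_frac[match(components[1],
                                             colnames(object$loadings))]),
      y = sprintf("%s (%.1f%%)", components[2],
                  100 * object$ev_frac[match(components[2],
                                             colnames(object$loadings))]),
      colour = "group") +
    ggplot2::theme_minimal()
}

#' Correlation heatmap of a stain pair
#'
#' Pearson r per parameter pair; significant cells (p below the matrix's
#' alpha) are outlined.
#'
#' @param object a `morph_cormat` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot morph_cormat
#' @export
autoplot.morph_cormat <- function(object, ...) {
  df <- tidy.morph_cormat(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter_b,
                                   y = .data$parameter_a,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[which(df$significant), ],
                       colour = "black", linewidth = 0.4, fill = NA) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = object$stains[2], y = object$stains[1],
                  title = sprintf("%s vs %s (%s): %d of %d significant",
                                  object$stains[1], object$stains[2],
                                  object$region, object$sig_count,
                                  object$n_computable)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}

#' Median comparison plot for one stain
#'
#' Group medians of each parameter with significance stars from the
#' Mann-Whitney battery.
#'
#' @param comparisons tibble from [compare_groups()].
#' @param stain stain to plot.
#' @param region region to plot (default hemispheric).
#' @return a ggplot object.
#' @export
plot_comparisons <- function(comparisons, stain,
                             region = "hemispheric") {
  df <- comparisons[comparisons$stain == stain &
                      comparisons$region == region, ]
  long <- tidyr::pivot_longer(
    df[, c("parameter", "median_NS", "median_S", "p")],
    cols = c("median_NS", "median_S"),
    names_to = "group", values_to = "median",
    names_prefix = "median_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter,
                                     y = .data$median,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ parameter, scales = "free") +
    ggplot2::labs(title = sprintf("%s (%s)", stain, region), x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
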