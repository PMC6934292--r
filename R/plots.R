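#' Molecular vs spatial heterogeneity scatter plot
#'
#' One point per sample x hallmark, molecular heterogeneity on the x axis
#' and spatial heterogeneity on the y axis, faceted by hallmark and
#' optionally colored by subject group.
#'
#' @param report A [heterogeneity_report()].
#' @param groups Optional named vector mapping `sample_id` to a group
#'   label, or a subjects tibble with `sample_id` and `group` columns.
#' @return A ggplot object.
#' @export
plot_heterogeneity <- function(report, groups = NULL) {
  df <- tibble::as_tibble(report)
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      groups <- setNames(groups$group, groups$sample_id)
    }
    df$group <- groups[df$sample_id]
  }
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$molecular_heterogeneity,
                 y = .data$spatial_heterogeneity)
  )
  p <- if ("group" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
  p +
    ggplot2::facet_wrap(~hallmark) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Molecular heterogeneity",
                  y = "Spatial heterogeneity") +
    ggplot2::theme_bw()
}

#' @exportS3Method ggplot2::autoplot
autoplot.heterogeneity_report <- function(object, ...) {
  plot_heterogeneity(object, ...)
}

#' Lollipop plot of cluster marker profiles
#'
#' Per cluster, each marker's mean deviation from the population average:
#' segments to the left are below-average expression, to the right above.
#' Facet labels carry the cluster's share of cells.
#'
#' @param profiles A [cluster_profiles()] result.
#' @return A ggplot object.
#' @export
plot_lollipop <- function(profiles) {
  df <- tibble::as_tibble(profiles)
  df$panel <- sprintf("cluster %d (%.1f%%)", df$cluster, df$pct_cells)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$deviation, y = .data$marker)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$deviation,
                                       yend = .data$marker)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "Deviation from population mean (standardized)",
                  y = NULL) +
    ggplot2::theme_bw()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cluster_profiles <- function(object, ...) plot_lollipop(object)

#' Consensus CDF plot
#'
#' Empirical CDF of the pairwise consensus values for each K; a curve
#' hugging the corners (mass near 0 and 1) marks a stable cluster number.
#'
#' @param consensus A [consensus_cluster()] result.
#' @return A ggplot object.
#' @export
plot_consensus_cdf <- function(consensus) {
  grid <- seq(0, 1, length.out = 101)
  df <- purrr::map(consensus$results, function(r) {
    tibble::tibble(k = r$k, consensus = grid, cdf = r$cdf(grid))
  })
  df <- dplyr::bind_rows(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$consensus, y = .data$cdf,
                                   color = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Consensus index", y = "CDF", color = "K") +
    ggplot2::theme_bw()
}

#' @exportS3Method ggplot2::autoplot
autoplot.consensus_result <- function(object, ...) plot_consensus_cdf(object)

#' Stacked-bar plot of per-sample cluster composition
#'
#' @param composition A [sample_composition()] result.
#' @return A ggplot object.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(
    tibble::as_tibble(composition),
    ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                 fill = factor(.data$cluster))
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of cells", fill = "Cluster") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.sample_composition <- function(object, ...) {
  plot_composition(object)
}
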