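#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a K-means scan
#'
#' @param x A [kmeans_scan()] result.
#' @param ... Unused.
#' @return The per-K metrics tibble (`k`, `sse`, `silhouette`, `calinski`).
#' @method tidy kmeans_scan
#' @export
tidy.kmeans_scan <- function(x, ...) x$metrics

#' @rdname tidy.kmeans_scan
#' @return For `glance()`: a one-row tibble with the silhouette-optimal K.
#' @method glance kmeans_scan
#' @export
glance.kmeans_scan <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$silhouette), ]
  tibble::tibble(best_k = best$k, best_silhouette = best$silhouette,
                 n_starts = x$n_starts, seed = x$seed)
}

#' Tidy a consensus-clustering result
#'
#' @param x A [consensus_cluster()] result.
#' @param ... Unused.
#' @return Per-K summary tibble from [consensus_summary()].
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) consensus_summary(x)

#' Tidy a quantization model
#'
#' @param x A `quantization_model`.
#' @param ... Unused.
#' @return Plain tibble of per-marker thresholds.
#' @method tidy quantization_model
#' @export
tidy.quantization_model <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "quantization_model")
  tibble::as_tibble(out)
}

#' Tidy an integration clustering
#'
#' @param x An [integrate_and_cluster()] result.
#' @param ... Unused.
#' @return Tibble of merge steps (`step`, `left`, `right`, `height`);
#'   negative entries index subjects (leaves), positive entries earlier
#'   merge steps, following `stats::hclust` conventions.
#' @method tidy integration_clust
#' @export
tidy.integration_clust <- function(x, ...) {
  tibble::tibble(
    step = seq_len(nrow(x$hclust$merge)),
    left = x$hclust$merge[, 1],
    right = x$hclust$merge[, 2],
    height = x$hclust$height
  )
}

#' Tidy a heterogeneity report
#'
#' @param x A [heterogeneity_report()].
#' @param ... Unused.
#' @return The scalar columns of the report (frequency list-columns
#'   dropped), ready for writing as a delimited table.
#' @method tidy heterogeneity_report
#' @export
tidy.heterogeneity_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$pm <- NULL
  out$ps <- NULL
  out
}

#' Summary of a k-choice report
#'
#' @param x A [choose_k()] result.
#' @param ... Unused.
#' @return One-row tibble with the chosen K and flag count.
#' @method glance k_choice
#' @export
glance.k_choice <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, n_flags = length(x$flags))
}
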