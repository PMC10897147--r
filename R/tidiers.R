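# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a group-comparison result
#'
#' @param x A `turnover_htest`.
#' @param ... Unused.
#' @return The pairwise post-hoc table as a tibble.
#' @method tidy turnover_htest
#' @export
tidy.turnover_htest <- function(x, ...) x$posthoc

#' @rdname tidy.turnover_htest
#' @return `glance()`: one-row tibble with the omnibus statistic.
#' @method glance turnover_htest
#' @export
glance.turnover_htest <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p.value = x$p.value, n = x$n, n_groups = length(x$groups))
}

#' Tidy a clustering result
#'
#' @param x A `turnover_clusters`.
#' @param ... Unused.
#' @return Per-protein labels and silhouette widths.
#' @method tidy turnover_clusters
#' @export
tidy.turnover_clusters <- function(x, ...) x$labels

#' @rdname tidy.turnover_clusters
#' @method glance turnover_clusters
#' @export
glance.turnover_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$labels),
                 mean_silhouette = x$mean_silhouette,
                 tot_withinss = x$tot_withinss, seed = x$seed)
}

#' Tidy a sample PCA
#'
#' @param x A `turnover_pca`.
#' @param ... Unused.
#' @return Sample coordinates (with any joined metadata).
#' @method tidy turnover_pca
#' @export
tidy.turnover_pca <- function(x, ...) x$coords

#' @rdname tidy.turnover_pca
#' @method glance turnover_pca
#' @export
glance.turnover_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coords), n_proteins = x$n_proteins,
    pc1_var = x$explained_variance[1], pc2_var = x$explained_variance[2]
  )
}
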