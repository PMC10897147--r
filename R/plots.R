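# ggplot2 views of the result types.

#' Plot FA distributions across age groups
#'
#' @param fa Long FA tibble (`protein`, `sample`, `fa`).
#' @param meta Sample metadata with `sample`, `age` and optionally `sex`.
#' @return A ggplot (boxplots of FA by age, faceted by sex when present).
#' @export
plot_fa_trends <- function(fa, meta) {
  d <- dplyr::inner_join(fa, meta, by = "sample")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$age), y = .data$fa)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "Age group (months)", y = "Fractional abundance") +
    ggplot2::theme_minimal()
  if ("sex" %in% names(d)) p <- p + ggplot2::facet_wrap(~sex)
  p
}

#' @method autoplot turnover_clusters
#' @export
autoplot.turnover_clusters <- function(object, ...) {
  centers <- tibble::as_tibble(object$centers, rownames = "cluster") |>
    tidyr::pivot_longer(!"cluster", names_to = "age", values_to = "z")
  ggplot2::ggplot(centers,
                  ggplot2::aes(x = .data$age, y = .data$z,
                               group = .data$cluster,
                               color = .data$cluster)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Age group (months)", y = "FA (row z-score)",
                  color = "Cluster",
                  title = sprintf("k-means trend centroids (k = %d)",
                                  object$k)) +
    ggplot2::theme_minimal()
}

#' @method autoplot turnover_pca
#' @export
autoplot.turnover_pca <- function(object, color = NULL, ...) {
  d <- object$coords
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(color) && color %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = factor(.data[[color]])),
                                 size = 2) +
      ggplot2::labs(color = color)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  ev <- object$explained_variance
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * ev[2])
  ) + ggplot2::theme_minimal()
}

#' @method autoplot turnover_diff
#' @export
autoplot.turnover_diff <- function(object, alpha = 0.05, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(.data$p.value),
                               color = .data$class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_color_manual(values = c(up = "red", down = "blue",
                                           ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot turnover_enrichment
#' @export
autoplot.turnover_enrichment <- function(object, top_n = 10, ...) {
  d <- rank_terms(object, top_n = top_n)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fold, y = .data$term,
                                  fill = -log10(.data$fdr))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Fold enrichment", y = NULL, fill = "-log10 FDR") +
    ggplot2::theme_minimal()
}

#' Plot an isotope envelope (optionally a mixed old/new pair)
#'
#' @param env An `isotope_envelope`.
#' @param ... Additional envelopes to overlay, named by legend label.
#' @return A ggplot of line abundances versus m/z.
#' @export
plot_envelope <- function(env, ...) {
  extra <- list(...)
  d <- dplyr::mutate(tibble::as_tibble(env),
                     species = attr(env, "label") %||% "envelope")
  for (nm in names(extra)) {
    d <- dplyr::bind_rows(d, dplyr::mutate(tibble::as_tibble(extra[[nm]]),
                                           species = nm))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mz, ymax = .data$abundance,
                                  ymin = 0, color = .data$species)) +
    ggplot2::geom_linerange(linewidth = 0.8) +
    ggplot2::labs(x = "m/z", y = "Relative abundance", color = NULL) +
    ggplot2::theme_minimal()
}
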