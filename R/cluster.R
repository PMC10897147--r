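# Trend clustering of FA profiles: row z-scoring, k-means with
# silhouette-based selection of k under a minimum cluster size, and PCA of
# replicate FA profiles.

#' Build a protein x age FA profile matrix
#'
#' Averages FA over replicates per protein and age (optionally within one sex
#' or fraction by pre-filtering `meta`) and pivots to one row per protein.
#'
#' @param fa Long FA tibble (`protein`, `sample`, value column).
#' @param meta Sample metadata with `sample` and `age`.
#' @param value Name of the value column (default `"fa"`).
#' @return Tibble with `protein` and one column per age (ascending).
#' @export
fa_profile_matrix <- function(fa, meta, value = "fa") {
  joined <- dplyr::inner_join(fa, meta, by = "sample")
  joined |>
    dplyr::group_by(.data$protein, .data$age) |>
    dplyr::summarise(v = mean(.data[[value]], na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$age) |>
    tidyr::pivot_wider(names_from = "age", values_from = "v")
}

#' Z-score matrix rows
#'
#' Per row: `(x - mean) / sd` with the n-1 (sample) standard deviation, the
#' convention of common heatmap tooling. Zero-variance rows cannot be scaled
#' and are dropped with a message.
#'
#' @param m Tibble whose first column is `protein` and remaining columns are
#'   numeric, or a plain numeric matrix with rownames.
#' @return Same shape with z-scored rows (zero-variance rows removed).
#' @export
#' @examples
#' zscore_rows(tibble::tibble(protein = "p", a = 1, b = 2, c = 3))
zscore_rows <- function(m) {
  if (is.data.frame(m)) {
    ids <- m$protein
    x <- as.matrix(m[setdiff(names(m), "protein")])
  } else {
    ids <- rownames(m)
    x <- m
  }
  if (ncol(x) < 2) rlang::abort("Need at least 2 columns to z-score.")
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  drop <- s == 0 | is.na(s)
  if (any(drop)) {
    rlang::inform(sprintf("Dropped %d zero-variance row(s).", sum(drop)))
  }
  z <- (x[!drop, , drop = FALSE] - mu[!drop]) / s[!drop]
  out <- tibble::as_tibble(z)
  tibble::add_column(out, protein = ids[!drop], .before = 1)
}

.as_cluster_matrix <- function(m) {
  if (is.data.frame(m)) {
    x <- as.matrix(m[setdiff(names(m), "protein")])
    rownames(x) <- m$protein
  } else {
    x <- as.matrix(m)
    if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  }
  x
}

#' K-means clustering of trend profiles
#'
#' Deterministic given `seed`: Euclidean k-means with `nstart` random
#' initializations and per-row silhouette widths.
#'
#' @param m Profile tibble (`protein` + numeric columns) or matrix, typically
#'   z-scored.
#' @param k Number of clusters (>= 2; `k = nrow` gives singletons).
#' @param seed Integer RNG seed (required for reproducibility).
#' @param nstart,iter_max K-means restarts and iteration cap.
#' @return A `turnover_clusters` object: `labels` tibble (protein, cluster,
#'   silhouette), `centers`, `k`, `seed`, `tot_withinss`.
#' @export
cluster_trends <- function(m, k, seed, nstart = 50, iter_max = 300) {
  x <- .as_cluster_matrix(m)
  if (k > nrow(x)) rlang::abort("`k` cannot exceed the number of rows.")
  if (k < 1) rlang::abort("`k` must be >= 1.")
  if (missing(seed)) rlang::abort("`seed` is required.")
  set.seed(seed)
  km <- if (k == nrow(x)) {
    # degenerate case: every row its own cluster
    list(cluster = setNames(seq_len(nrow(x)), rownames(x)), centers = x,
         tot.withinss = 0)
  } else {
    kmeans(x, centers = k, nstart = nstart, iter.max = iter_max)
  }
  sil <- if (k >= 2 && k < nrow(x)) {
    cluster::silhouette(km$cluster, stats::dist(x))[, "sil_width"]
  } else {
    rep(NA_real_, nrow(x))
  }
  structure(
    list(
      labels = tibble::tibble(protein = rownames(x),
                              cluster = unname(km$cluster),
                              silhouette = as.numeric(sil)),
      centers = km$centers, k = k, seed = seed,
      tot_withinss = km$tot.withinss,
      mean_silhouette = mean(as.numeric(sil))
    ),
    class = "turnover_clusters"
  )
}

#' Select the number of clusters by silhouette under a size constraint
#'
#' Runs k-means for each candidate k (same seed, `nstart` restarts), computes
#' the mean Euclidean silhouette, discards solutions with any cluster smaller
#' than `min_size`, and keeps the k with the highest mean silhouette (ties go
#' to the smaller k).
#'
#' @inheritParams cluster_trends
#' @param k_range Candidate k values (default 2:8).
#' @param min_size Minimum admissible cluster size (default 10).
#' @return A `turnover_clusters` for the chosen k with a `silhouette_curve`
#'   tibble (`k`, `mean_silhouette`, `min_cluster_size`, `admissible`).
#' @export
select_k <- function(m, k_range = 2:8, min_size = 10, seed, nstart = 50,
                     iter_max = 300) {
  x <- .as_cluster_matrix(m)
  k_range <- k_range[k_range >= 2 & k_range <= nrow(x) - 1]
  if (length(k_range) == 0) rlang::abort("`k_range` is empty after bounds.")
  if (missing(seed)) rlang::abort("`seed` is required.")
  fits <- purrr::map(k_range, function(k) {
    cluster_trends(x, k, seed = seed, nstart = nstart, iter_max = iter_max)
  })
  curve <- tibble::tibble(
    k = k_range,
    mean_silhouette = vapply(fits, function(f) f$mean_silhouette, numeric(1)),
    min_cluster_size = vapply(fits, function(f) {
      min(table(f$labels$cluster))
    }, numeric(1))
  )
  curve$admissible <- curve$min_cluster_size >= min_size
  if (!any(curve$admissible)) {
    rlang::abort("No k in `k_range` satisfies the minimum cluster size.")
  }
  ok <- which(curve$admissible)
  best <- ok[which.max(curve$mean_silhouette[ok])]  # ties -> smaller k
  out <- fits[[best]]
  out$silhouette_curve <- curve
  out$min_size <- min_size
  out
}

#' @export
print.turnover_clusters <- function(x, ...) {
  cat(sprintf("<turnover_clusters> k = %d, %d proteins, mean silhouette %.3f\n",
              x$k, nrow(x$labels), x$mean_silhouette))
  print(table(x$labels$cluster))
  invisible(x)
}

#' PCA of replicate FA profiles
#'
#' Centered (unscaled) principal component analysis of samples in protein
#' space, restricted to complete-case proteins.
#'
#' @param fa Long FA tibble (`protein`, `sample`, `fa`).
#' @param meta Optional sample metadata joined onto the coordinates.
#' @param n_components Number of PCs to keep.
#' @return A `turnover_pca`: `coords` tibble (sample, PC columns, metadata),
#'   `explained_variance` ratios, `n_proteins`.
#' @export
pca_samples <- function(fa, meta = NULL, n_components = 5) {
  wide <- fa |>
    dplyr::select("protein", "sample", "fa") |>
    tidyr::pivot_wider(names_from = "protein", values_from = "fa")
  x <- as.matrix(wide[setdiff(names(wide), "sample")])
  keep <- colSums(is.na(x)) == 0
  if (sum(keep) < 2) rlang::abort("Fewer than 2 complete-case proteins.")
  if (nrow(x) < 3) rlang::abort("Need at least 3 samples.")
  x <- x[, keep, drop = FALSE]
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  n_pc <- min(n_components, ncol(p$x))
  coords <- tibble::as_tibble(p$x[, seq_len(n_pc), drop = FALSE])
  coords <- tibble::add_column(coords, sample = wide$sample, .before = 1)
  if (!is.null(meta)) coords <- dplyr::left_join(coords, meta, by = "sample")
  structure(
    list(coords = coords,
         explained_variance = p$sdev^2 / sum(p$sdev^2),
         n_proteins = sum(keep)),
    class = "turnover_pca"
  )
}

#' @export
print.turnover_pca <- function(x, ...) {
  cat(sprintf("<turnover_pca> %d samples x %d complete-case proteins\n",
              nrow(x$coords), x$n_proteins))
  ev <- x$explained_variance[seq_len(min(3, length(x$explained_variance)))]
  cat("  explained variance:", paste0(sprintf("%.1f%%", 100 * ev),
                                      collapse = ", "), "\n")
  invisible(x)
}
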