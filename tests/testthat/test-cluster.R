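# Row z-scoring, silhouette-guided k selection and PCA.

test_that("z-scored rows have mean 0 and unit (n-1) sd", {
  m <- tibble::tibble(protein = c("a", "b", "c"),
                      x = c(1, 5, 2), y = c(2, 5, 2), z = c(3, 5, 2))
  expect_message(out <- zscore_rows(m), "zero-variance")
  expect_equal(out$protein, "a")           # constant rows dropped
  expect_equal(as.numeric(out[1, -1]), c(-1, 0, 1))

  set.seed(3)
  big <- tibble::tibble(protein = paste0("p", 1:30))
  for (cn in letters[1:5]) big[[cn]] <- rnorm(30)
  z <- as.matrix(zscore_rows(big)[, -1])
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)

  # an already standardized row is unchanged
  std <- tibble::tibble(protein = "a", x = -1, y = 0, z = 1)
  expect_equal(as.numeric(zscore_rows(std)[, -1]), c(-1, 0, 1),
               tolerance = 1e-12)
  expect_error(zscore_rows(tibble::tibble(protein = "a", x = 1)), "2 columns")
})

test_that("silhouette selection recovers forced geometry and obeys min size", {
  set.seed(10)
  blobs <- rbind(matrix(rnorm(40 * 5, 0), ncol = 5),
                 matrix(rnorm(40 * 5, 10), ncol = 5))
  rownames(blobs) <- paste0("p", 1:80)
  res <- select_k(blobs, k_range = 2:6, min_size = 10, seed = 99)
  expect_equal(res$k, 2)
  expect_true(all(res$silhouette_curve$mean_silhouette[-1] <
                    res$silhouette_curve$mean_silhouette[1]))
  # min_size larger than any admissible split
  expect_error(select_k(blobs, k_range = 3:6, min_size = 40, seed = 99),
               "minimum cluster size")
})

test_that("silhouette widths match the brute-force oracle", {
  set.seed(17)
  x <- rbind(matrix(rnorm(60, 0), ncol = 3),
             matrix(rnorm(60, 3), ncol = 3),
             matrix(rnorm(30, -3), ncol = 3))
  rownames(x) <- paste0("p", 1:50)
  fit <- cluster_trends(x, k = 3, seed = 5)
  ora <- oracle_silhouette(x, fit$labels$cluster)
  expect_lt(max(abs(fit$labels$silhouette - ora)), 1e-9)
  expect_equal(fit$mean_silhouette, mean(ora), tolerance = 1e-9)
})

test_that("k-means clustering is deterministic and permutation sane", {
  set.seed(20)
  x <- matrix(rnorm(40 * 4), ncol = 4)
  rownames(x) <- paste0("p", 1:40)
  f1 <- cluster_trends(x, 3, seed = 7)
  f2 <- cluster_trends(x, 3, seed = 7)
  expect_identical(f1$labels, f2$labels)

  # duplicated rows land in the same cluster
  dup <- rbind(x, x[1, , drop = FALSE])
  rownames(dup) <- c(rownames(x), "dup")
  fd <- cluster_trends(dup, 3, seed = 7)
  lab <- fd$labels
  expect_equal(lab$cluster[lab$protein == "dup"],
               lab$cluster[lab$protein == "p1"])

  # row order invariance up to label permutation
  perm <- sample(nrow(x))
  fp <- cluster_trends(x[perm, ], 3, seed = 7)
  skip_if_not_installed("mclust")
  m <- dplyr::inner_join(f1$labels, fp$labels, by = "protein")
  expect_equal(mclust::adjustedRandIndex(m$cluster.x, m$cluster.y), 1)

  # k = n gives singletons with zero inertia
  fs <- cluster_trends(x[1:6, ], 6, seed = 7)
  expect_equal(fs$tot_withinss, 0)
  expect_equal(sort(fs$labels$cluster), 1:6)
  expect_error(cluster_trends(x, 50, seed = 7), "exceed")
  expect_error(cluster_trends(x, 3), "seed")
})

test_that("planted archetypes are recovered from the synthetic cohort", {
  skip_if_not_installed("mclust")
  pan <- protein_panel(250, seed = 33)
  truth <- simulate_truth(cohort_design(seed = 33), pan)
  fa <- truth$sample_truth |>
    dplyr::filter(.data$sex == "male") |>
    dplyr::transmute(protein = .data$protein, sample = .data$sample,
                     fa = .data$fa_sample)
  prof <- fa_profile_matrix(fa, truth$samples)
  res <- select_k(zscore_rows(prof), k_range = 2:8, min_size = 10, seed = 101)
  expect_equal(res$k, 5)
  m <- dplyr::inner_join(tidy(res), pan[, c("protein", "archetype")],
                         by = "protein")
  expect_gte(mclust::adjustedRandIndex(m$cluster, m$archetype), 0.9)
})

test_that("sample PCA matches the covariance eigendecomposition", {
  set.seed(40)
  n_s <- 12; n_p <- 30
  fa <- tidyr::expand_grid(protein = paste0("p", 1:n_p),
                           sample = paste0("s", 1:n_s)) |>
    dplyr::mutate(fa = runif(dplyr::n()))
  pc <- pca_samples(fa)
  # rebuild the samples x proteins matrix the same way the function does
  wide <- tidyr::pivot_wider(fa, names_from = "protein", values_from = "fa")
  xm <- as.matrix(wide[, -1])
  ev <- eigen(stats::cov(xm))$values
  expect_equal(pc$explained_variance[1:10], (ev / sum(ev))[1:10],
               tolerance = 1e-9)
  expect_lte(sum(pc$explained_variance), 1 + 1e-12)

  # identical samples collapse to the same coordinates
  fa2 <- fa
  fa2$fa[fa2$sample == "s2"] <- fa2$fa[fa2$sample == "s1"]
  pc2 <- pca_samples(fa2)
  c12 <- as.matrix(pc2$coords[pc2$coords$sample %in% c("s1", "s2"), -1])
  expect_lt(max(abs(c12[1, ] - c12[2, ])), 1e-9)
  expect_error(pca_samples(fa[fa$sample %in% c("s1", "s2"), ]), "3 samples")
})

test_that("age groups separate in PC space for the synthetic cohort", {
  pan <- protein_panel(250, seed = 44)
  truth <- simulate_truth(cohort_design(seed = 44), pan)
  fa <- truth$sample_truth |>
    dplyr::filter(.data$sex == "male") |>
    dplyr::transmute(protein = .data$protein, sample = .data$sample,
                     fa = .data$fa_sample)
  pc <- pca_samples(fa, truth$samples)
  co <- pc$coords
  d <- as.matrix(dist(co[, c("PC1", "PC2")]))
  same_age <- outer(co$age, co$age, `==`) & upper.tri(d)
  diff_age <- outer(co$age, co$age, `!=`) & upper.tri(d)
  expect_lt(mean(d[same_age]), mean(d[diff_age]))
})
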