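# Rollup, NSAF, group statistics, reference adjustment, complex comparison,
# differential abundance.

test_that("rollup is area-weighted and bounded by member-peptide FA", {
  one <- tibble::tibble(protein = "p", i_old = 3, i_new = 7)
  expect_equal(rollup_protein_fa(one)$fa, 0.3)

  two <- tibble::tibble(protein = "p", i_old = c(10, 30), i_new = c(90, 70))
  expect_equal(rollup_protein_fa(two)$fa, 0.2)
  expect_equal(rollup_protein_fa(two, method = "mean_fa")$fa,
               mean(c(0.1, 0.3)))

  set.seed(2)
  many <- tibble::tibble(protein = rep(letters[1:5], each = 4),
                         i_old = runif(20, 0, 100),
                         i_new = runif(20, 0, 100))
  rolled <- rollup_protein_fa(many)
  pep_fa <- many |>
    dplyr::mutate(fa = i_old / (i_old + i_new)) |>
    dplyr::group_by(protein) |>
    dplyr::summarise(lo = min(fa), hi = max(fa))
  chk <- dplyr::inner_join(rolled, pep_fa, by = "protein")
  expect_true(all(chk$fa >= chk$lo & chk$fa <= chk$hi))
  expect_error(rollup_protein_fa(many[0, ]), "No peptides")
})

test_that("replicate filter drops protein-group pairs below the threshold", {
  fa <- tibble::tibble(protein = c(rep("a", 4), rep("b", 2)),
                       sample = c(paste0("s", 1:4), "s1", "s2"),
                       fa = 0.5)
  meta <- tibble::tibble(sample = paste0("s", 1:4), age = 12)
  out <- require_min_replicates(fa, meta, "age", min_replicates = 3)
  expect_setequal(unique(out$protein), "a")
})

test_that("NSAF is length-corrected, normalized and scale invariant", {
  expect_equal(nsaf(tibble::tibble(protein = "a", spectral_counts = 7,
                                   length = 300))$nsaf, 1)
  two <- nsaf(tibble::tibble(protein = c("a", "b"),
                             spectral_counts = c(10, 20),
                             length = c(100, 400)))
  expect_equal(two$nsaf, c(2 / 3, 1 / 3))

  set.seed(8)
  d <- tibble::tibble(protein = paste0("p", 1:50),
                      spectral_counts = rpois(50, 20),
                      length = sample(100:900, 50))
  expect_equal(sum(nsaf(d)$nsaf), 1, tolerance = 1e-12)
  expect_equal(nsaf(dplyr::mutate(d, spectral_counts = spectral_counts * 2))$nsaf,
               nsaf(d)$nsaf)
  expect_error(nsaf(dplyr::mutate(d, spectral_counts = 0)), "zero")
})

test_that("t and Kruskal-Wallis outputs match closed forms", {
  d <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  st <- compare_groups(d, "v", "g", method = "student")
  ora <- oracle_student_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(st$statistic, ora$t, tolerance = 1e-12)
  expect_equal(st$p.value, ora$p, tolerance = 1e-12)

  kw_d <- data.frame(v = 1:6, g = rep(c("a", "b", "c"), each = 2))
  kw <- compare_groups(kw_d, "v", "g", method = "kruskal")
  expect_equal(kw$statistic,
               oracle_kw_h(list(c(1, 2), c(3, 4), c(5, 6))),
               tolerance = 1e-12)
  expect_equal(nrow(tidy(kw)), 3)        # all pairwise contrasts
  expect_true(all(tidy(kw)$adj.p.value >= tidy(kw)$p.value - 1e-15))

  # identical groups: zero statistic
  same <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(compare_groups(same, "v", "g", method = "kruskal")$statistic, 0)

  expect_error(compare_groups(data.frame(v = 1:2, g = c("a", "b")), "v", "g"),
               ">= 2 observations")
})

test_that("one-way ANOVA agrees with a permutation oracle on toy data", {
  set.seed(31)
  d <- data.frame(v = c(rnorm(8, 0), rnorm(8, 0.5), rnorm(8, 0.4)),
                  g = rep(c("a", "b", "c"), each = 8))
  res <- compare_groups(d, "v", "g", method = "anova")
  f_obs <- res$statistic
  f_perm <- replicate(4000, {
    summary(aov(sample(d$v) ~ d$g))[[1]][["F value"]][1]
  })
  p_perm <- mean(f_perm >= f_obs)
  expect_lt(abs(p_perm - res$p.value),
            0.03 + 3 * sqrt(res$p.value * (1 - res$p.value) / 4000))
})

test_that("two-way ANOVA and Welch t run with per-term output", {
  set.seed(5)
  d <- data.frame(v = rnorm(40), g = rep(c("x", "y"), 20),
                  h = rep(c("u", "v"), each = 20))
  tw <- compare_groups(d, "v", "g", group2 = "h", method = "twoway")
  expect_equal(tw$terms$term, c("g", "g2", "g:g2"))
  expect_true(all(tw$terms$p.value >= 0 & tw$terms$p.value <= 1))
  w <- compare_groups(d, "v", "g", method = "welch")
  expect_s3_class(glance(w), "tbl_df")
})

test_that("median adjustment centers the reference and keeps differences", {
  fa <- tibble::tibble(
    protein = rep("p", 5),
    sample = paste0("s", 1:5),
    fa = c(0.2, 0.3, 0.4, 0.25, 0.35)
  )
  adj <- median_adjust(fa, ref_samples = paste0("s", 1:3))
  expect_equal(adj$fa_adj[1:3], c(-0.1, 0, 0.1))
  # reference group median of adjusted values is zero
  expect_equal(median(adj$fa_adj[1:3]), 0)
  # pairwise within-row differences unchanged
  expect_equal(diff(adj$fa_adj), diff(fa$fa))

  other <- tibble::tibble(protein = "q", sample = "s4", fa = 0.9)
  both <- median_adjust(dplyr::bind_rows(fa, other), paste0("s", 1:3))
  expect_true(both$ref_missing[both$protein == "q"])
  expect_true(is.na(both$fa_adj[both$protein == "q"]))
  expect_error(median_adjust(fa, "nope"), "absent")
})

test_that("complex comparison detects a planted 19S/20S FA offset", {
  cx <- proteasome_complexes()
  meta <- tidyr::expand_grid(age = c(12, 15, 18, 21, 24), replicate = 1:4) |>
    dplyr::mutate(sample = paste0("s", dplyr::row_number()))
  set.seed(9)
  fa <- tidyr::expand_grid(protein = cx$gene, sample = meta$sample) |>
    dplyr::left_join(cx, by = c(protein = "gene")) |>
    dplyr::mutate(fa = 0.3 + ifelse(complex == "19S", 0.1, 0) +
                    rnorm(dplyr::n(), 0, 0.03)) |>
    dplyr::select(protein, sample, fa)
  res <- complex_compare(fa, meta)
  expect_gt(res$effect, 0)            # 19S above 20S
  expect_lt(res$p.value, 0.001)
  expect_equal(nrow(res$per_age), 5)
  expect_true(all(res$per_age$estimate > 0))

  # identical complexes: effect ~ 0, p not significant
  fa0 <- dplyr::mutate(fa, fa = 0.3)
  same <- suppressWarnings(complex_compare(dplyr::mutate(
    fa, fa = 0.3 + rnorm(dplyr::n(), 0, 1e-6)), meta))
  expect_lt(abs(same$effect), 1e-6)

  expect_error(complex_compare(fa[fa$protein == "Psma1", ], meta), "members")
})

test_that("differential abundance classifies planted fold changes", {
  set.seed(12)
  n_prot <- 500; n_up <- 50
  proteins <- sprintf("p%03d", seq_len(n_prot))
  arms <- tibble::tibble(sample = paste0("s", 1:10),
                         arm = rep(c("t", "c"), each = 5))
  base <- rlnorm(n_prot, log(1e5), 0.5)
  d <- tidyr::expand_grid(protein = proteins, sample = arms$sample) |>
    dplyr::left_join(arms, by = "sample") |>
    dplyr::mutate(
      fold = ifelse(protein %in% proteins[1:n_up] & arm == "t", 2, 1),
      abundance = base[match(protein, proteins)] * fold *
        rlnorm(dplyr::n(), 0, 0.15)
    )
  res <- diff_abundance(d[, c("protein", "sample", "abundance")], arms,
                        "t", "c")
  planted <- res$class[res$protein %in% proteins[1:n_up]]
  expect_gte(sum(planted == "up"), 45)
  fp <- sum(res$class[!res$protein %in% proteins[1:n_up]] != "ns")
  expect_lte(fp, 2)

  # identical arms: everything ns
  same <- dplyr::mutate(d, abundance = base[match(protein, proteins)] *
                          rlnorm(dplyr::n(), 0, 0.1))
  res0 <- diff_abundance(same[, c("protein", "sample", "abundance")], arms,
                         "t", "c", alpha = 0.05)
  expect_true(all(res0$class == "ns"))

  # constant arms: log2FC exact, flagged zero-variance
  flat <- tibble::tibble(protein = "p", sample = arms$sample) |>
    dplyr::left_join(arms, by = "sample") |>
    dplyr::mutate(abundance = ifelse(arm == "t", 4, 2))
  r <- diff_abundance(flat[, c("protein", "sample", "abundance")], arms,
                      "t", "c")
  expect_equal(r$log2fc, 1)
  expect_equal(r$flag, "zero_variance")
})
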