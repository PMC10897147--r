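# Protein-level rollup, NSAF abundance, group statistics, reference-group
# adjustment, proteasome-complex comparisons and differential abundance.

#' Packaged proteasome complex definitions
#'
#' Member gene symbols of the 20S core particle (Psma1-7, Psmb1-7) and the
#' 19S regulatory particle (Psmc1-6, Psmd1-14); [catalytic_subunits()] returns
#' the proteolytically active 20S subunits.
#'
#' @return Tibble with columns `complex` (`"20S"`/`"19S"`) and `gene`.
#' @export
#' @examples
#' proteasome_complexes()
proteasome_complexes <- function() {
  tibble::tibble(
    complex = c(rep("20S", 14), rep("19S", 20)),
    gene = c(paste0("Psma", 1:7), paste0("Psmb", 1:7),
             paste0("Psmc", 1:6), paste0("Psmd", 1:14))
  )
}

#' @rdname proteasome_complexes
#' @export
catalytic_subunits <- function() c("Psmb1", "Psmb2", "Psmb5")

#' Roll peptide turnover up to protein fractional abundance
#'
#' Protein FA per sample is the area-weighted pool ratio
#' `sum(i_old) / (sum(i_old) + sum(i_new))` over the protein's peptides
#' (`method = "area"`, the default, matching chromatogram-area
#' quantification), or the unweighted mean of peptide FA
#' (`method = "mean_fa"`).
#'
#' @param peptides Peptide-turnover tibble with columns `protein`, `i_old`,
#'   `i_new` and optionally `sample` (rollup is per sample when present).
#' @param method `"area"` or `"mean_fa"`.
#' @param min_peptides Minimum peptides per protein/sample.
#' @return Tibble with `protein`, (`sample`,) `n_peptides`, `fa`.
#' @export
rollup_protein_fa <- function(peptides, method = c("area", "mean_fa"),
                              min_peptides = 1) {
  method <- match.arg(method)
  req <- c("protein", "i_old", "i_new")
  if (!is.data.frame(peptides) || !all(req %in% names(peptides))) {
    rlang::abort("`peptides` needs columns protein, i_old, i_new.")
  }
  if (nrow(peptides) == 0) rlang::abort("No peptides to roll up.")
  grp <- if ("sample" %in% names(peptides)) c("protein", "sample") else "protein"
  out <- peptides |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_peptides = dplyr::n(),
      fa = if (method == "area") {
        sum(.data$i_old) / (sum(.data$i_old) + sum(.data$i_new))
      } else {
        mean(.data$i_old / (.data$i_old + .data$i_new))
      },
      .groups = "drop"
    )
  out[out$n_peptides >= min_peptides, , drop = FALSE]
}

#' Drop proteins seen in too few replicates of a group
#'
#' @param fa Long FA tibble (`protein`, `sample`, `fa`).
#' @param meta Sample metadata with `sample` and the grouping columns.
#' @param group_vars Metadata columns defining a group (e.g. `c("age","sex")`).
#' @param min_replicates Minimum samples of a group a protein must be
#'   measured in; protein x group combinations below this are removed.
#' @return Filtered FA tibble.
#' @export
require_min_replicates <- function(fa, meta, group_vars, min_replicates = 3) {
  joined <- dplyr::inner_join(fa, meta, by = "sample")
  keep <- joined |>
    dplyr::filter(!is.na(.data$fa)) |>
    dplyr::count(.data$protein,
                 dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::filter(.data$n >= min_replicates) |>
    dplyr::select(!"n")
  joined |>
    dplyr::semi_join(keep, by = c("protein", group_vars)) |>
    dplyr::select(dplyr::all_of(names(fa)))
}

#' Normalized spectral abundance factor
#'
#' `NSAF_i = (SpC_i / L_i) / sum_j(SpC_j / L_j)`: spectral counts corrected
#' for protein length and normalized so abundances sum to 1.
#'
#' @param counts Tibble with columns `protein`, `spectral_counts`, `length`
#'   (residues).
#' @return The tibble with an added `nsaf` column.
#' @export
#' @examples
#' nsaf(tibble::tibble(protein = c("a", "b"),
#'                     spectral_counts = c(10, 20), length = c(100, 400)))
nsaf <- function(counts) {
  req <- c("protein", "spectral_counts", "length")
  if (!is.data.frame(counts) || !all(req %in% names(counts))) {
    rlang::abort("`counts` needs columns protein, spectral_counts, length.")
  }
  if (any(counts$spectral_counts < 0) || any(counts$length <= 0)) {
    rlang::abort("Counts must be >= 0 and lengths > 0.")
  }
  saf <- counts$spectral_counts / counts$length
  if (sum(saf) == 0) rlang::abort("All spectral counts are zero.")
  dplyr::mutate(tibble::as_tibble(counts), nsaf = saf / sum(saf))
}

# hand-rolled Dunn post-hoc (no installed package provides it): pairwise
# rank-sum z tests with the Kruskal-Wallis pooled-rank variance and tie
# correction, BH-adjusted by default.
.dunn_test <- function(x, g, adjust = "BH") {
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  groups <- levels(g)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  pairs <- utils::combn(groups, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[p[1]] + 1 / ni[p[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    estimate = as.numeric(rbar[pairs[1, ]] - rbar[pairs[2, ]]),
    statistic = as.numeric(z), p.value = as.numeric(p),
    adj.p.value = p.adjust(p, adjust)
  )
}

.tukey_tibble <- function(fit, term) {
  tk <- TukeyHSD(fit)[[term]]
  parts <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble::tibble(
    group1 = vapply(parts, `[`, "", 1),
    group2 = vapply(parts, `[`, "", 2),
    estimate = tk[, "diff"], conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
    adj.p.value = tk[, "p adj"]
  )
}

#' Compare FA (or any response) across groups
#'
#' Omnibus test plus a pairwise post-hoc table. Methods: one-way ANOVA with
#' Tukey HSD (`"anova"`); Kruskal-Wallis with Dunn's pairwise rank-sum z tests
#' (BH-adjusted; the statistically standard pairing) or, to mirror common
#' figure-legend practice, Tukey HSD on ranks (`posthoc = "tukey_ranks"`);
#' two-way ANOVA for a factorial design (`"twoway"`, give `group2`); Welch or
#' Student two-sample t (`"welch"`, `"student"`).
#'
#' @param data A data frame.
#' @param value,group,group2 Column names (strings) of the response and
#'   grouping factor(s).
#' @param method One of `"anova"`, `"kruskal"`, `"twoway"`, `"welch"`,
#'   `"student"`.
#' @param posthoc For `"kruskal"`: `"dunn"` (default) or `"tukey_ranks"`.
#' @return A `turnover_htest` object; see [tidy()][generics::tidy] /
#'   [glance()][generics::glance].
#' @export
#' @examples
#' d <- data.frame(fa = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' compare_groups(d, "fa", "g", method = "student")
compare_groups <- function(data, value, group, group2 = NULL,
                           method = c("anova", "kruskal", "twoway", "welch",
                                      "student"),
                           posthoc = c("dunn", "tukey_ranks")) {
  method <- match.arg(method)
  posthoc <- match.arg(posthoc)
  x <- data[[value]]
  g <- factor(data[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) rlang::abort("Need at least 2 groups.")
  if (any(table(g) < 2)) rlang::abort("Every group needs >= 2 observations.")

  if (method == "anova") {
    fit <- aov(x ~ g)
    s <- summary(fit)[[1]]
    res <- list(method = "one-way ANOVA + Tukey HSD",
                statistic = s[["F value"]][1], p.value = s[["Pr(>F)"]][1],
                parameter = s[["Df"]][1:2],
                posthoc = .tukey_tibble(fit, "g"), adjustment = "Tukey")
  } else if (method == "kruskal") {
    kw <- kruskal.test(x, g)
    ph <- if (posthoc == "dunn") {
      .dunn_test(x, g)
    } else {
      .tukey_tibble(aov(rank(x) ~ g), "g")
    }
    res <- list(method = paste0("Kruskal-Wallis + ",
                                if (posthoc == "dunn") "Dunn (BH)" else
                                  "Tukey on ranks"),
                statistic = unname(kw$statistic), p.value = kw$p.value,
                parameter = unname(kw$parameter), posthoc = ph,
                adjustment = if (posthoc == "dunn") "BH" else "Tukey")
  } else if (method == "twoway") {
    if (is.null(group2)) rlang::abort("`group2` is required for `twoway`.")
    g2 <- factor(data[[group2]][ok])
    fit <- aov(x ~ g * g2)
    s <- summary(fit)[[1]]
    terms <- trimws(rownames(s))
    omni <- tibble::tibble(term = terms[-length(terms)],
                           statistic = s[["F value"]][-nrow(s)],
                           p.value = s[["Pr(>F)"]][-nrow(s)])
    res <- list(method = "two-way ANOVA", statistic = omni$statistic[1],
                p.value = omni$p.value[1], parameter = s[["Df"]],
                posthoc = .tukey_tibble(fit, "g"), terms = omni,
                adjustment = "Tukey")
  } else {
    if (nlevels(g) != 2) rlang::abort("t tests need exactly 2 groups.")
    tt <- t.test(x ~ g, var.equal = method == "student")
    res <- list(method = if (method == "welch") "Welch t" else "Student t",
                statistic = unname(tt$statistic), p.value = tt$p.value,
                parameter = unname(tt$parameter),
                posthoc = tibble::tibble(
                  group1 = levels(g)[1], group2 = levels(g)[2],
                  estimate = unname(diff(rev(tt$estimate))),
                  statistic = unname(tt$statistic), p.value = tt$p.value,
                  adj.p.value = tt$p.value),
                adjustment = "none")
  }
  res$n <- length(x)
  res$groups <- levels(g)
  structure(res, class = "turnover_htest")
}

#' @export
print.turnover_htest <- function(x, ...) {
  cat("<turnover_htest> ", x$method, "\n", sep = "")
  cat(sprintf("  statistic = %.4g, p = %.4g (n = %d, %d groups)\n",
              x$statistic, x$p.value, x$n, length(x$groups)))
  cat("  post-hoc pairs:", nrow(x$posthoc), "\n")
  invisible(x)
}

#' Adjust FA to the median of a reference group
#'
#' Subtracts, per protein, the median FA over the reference samples (the
#' difference form, so later row z-scoring is unaffected by the choice of
#' form). Proteins with no finite reference value are flagged and get `NA`.
#'
#' @param fa Long FA tibble (`protein`, `sample`, `fa`).
#' @param ref_samples Character vector of reference-group sample ids.
#' @return The tibble with `fa_adj` and `ref_missing` columns.
#' @export
median_adjust <- function(fa, ref_samples) {
  if (!all(c("protein", "sample", "fa") %in% names(fa))) {
    rlang::abort("`fa` needs columns protein, sample, fa.")
  }
  if (!any(fa$sample %in% ref_samples)) {
    rlang::abort("Reference group absent from `fa`.")
  }
  ref <- fa |>
    dplyr::filter(.data$sample %in% ref_samples) |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(ref_median = stats::median(.data$fa, na.rm = TRUE),
                     .groups = "drop")
  fa |>
    dplyr::left_join(ref, by = "protein") |>
    dplyr::mutate(
      ref_missing = is.na(.data$ref_median),
      fa_adj = .data$fa - .data$ref_median
    ) |>
    dplyr::select(!"ref_median")
}

#' Compare proteasome complexes across ages
#'
#' Pools member-protein FA values per complex and compares the 19S regulatory
#' particle against the 20S core by two-way ANOVA (complex x age), with
#' per-age Welch t tests and the overall mean FA difference (19S - 20S).
#'
#' @param fa Long FA tibble (`protein` = gene symbol, `sample`, `fa`).
#' @param meta Sample metadata with `sample` and `age`.
#' @param complexes Complex definitions; default [proteasome_complexes()].
#' @return A `turnover_htest` with `per_age` and `effect` elements.
#' @export
complex_compare <- function(fa, meta, complexes = proteasome_complexes()) {
  d <- fa |>
    dplyr::inner_join(meta, by = "sample") |>
    dplyr::inner_join(complexes, by = c(protein = "gene")) |>
    dplyr::filter(!is.na(.data$fa))
  n_members <- d |>
    dplyr::distinct(.data$complex, .data$protein) |>
    dplyr::count(.data$complex)
  missing <- setdiff(unique(complexes$complex), n_members$complex)
  if (length(missing) > 0 || any(n_members$n < 2)) {
    rlang::abort("Each complex needs >= 2 measured members.")
  }
  res <- compare_groups(d, "fa", "complex", group2 = "age", method = "twoway")
  res$per_age <- d |>
    dplyr::group_by(.data$age) |>
    dplyr::group_modify(function(g, key) {
      tt <- t.test(fa ~ complex, data = g)
      tibble::tibble(estimate = unname(diff(rev(tt$estimate))),
                     statistic = unname(tt$statistic), p.value = tt$p.value)
    }) |>
    dplyr::ungroup()
  means <- tapply(d$fa, d$complex, mean)
  res$effect <- unname(means["19S"] - means["20S"])
  res$method <- "complex comparison (two-way ANOVA complex x age)"
  res
}

#' Differential abundance between two arms (volcano classification)
#'
#' Per-protein Welch t test on log2 abundances between arm A and arm B with
#' BH adjustment across proteins; proteins are classified `"up"` when
#' adjusted p < alpha and log2FC > 0 (A over B), `"down"` when adjusted
#' p < alpha and log2FC < 0, otherwise `"ns"`. Zero-variance degenerate
#' proteins are flagged and left unclassified.
#'
#' @param abund Long abundance tibble (`protein`, `sample`, `abundance`).
#' @param arms Tibble mapping `sample` to `arm`.
#' @param arm_a,arm_b Arm labels; log2FC is `mean(log2 A) - mean(log2 B)`.
#' @param alpha Significance level on the BH-adjusted p.
#' @param adjust Multiplicity adjustment method (see [stats::p.adjust()]);
#'   `"none"` uses raw p values.
#' @param log2_transform Take log2 of abundances first (default TRUE).
#' @return Tibble: `protein`, `log2fc`, `statistic`, `p.value`, `adj.p.value`,
#'   `class`, `flag`.
#' @export
diff_abundance <- function(abund, arms, arm_a, arm_b, alpha = 0.05,
                           adjust = "BH", log2_transform = TRUE) {
  d <- abund |>
    dplyr::inner_join(arms, by = "sample") |>
    dplyr::filter(.data$arm %in% c(arm_a, arm_b), !is.na(.data$abundance))
  if (log2_transform) d$abundance <- log2(d$abundance)
  counts <- d |> dplyr::count(.data$protein, .data$arm)
  if (any(counts$n < 2)) {
    rlang::abort("Every protein needs >= 2 replicates per arm.")
  }
  res <- d |>
    dplyr::group_by(.data$protein) |>
    dplyr::group_modify(function(g, key) {
      xa <- g$abundance[g$arm == arm_a]
      xb <- g$abundance[g$arm == arm_b]
      l2fc <- mean(xa) - mean(xb)
      if (sd(xa) == 0 && sd(xb) == 0) {
        return(tibble::tibble(log2fc = l2fc, statistic = NA_real_,
                              p.value = NA_real_, flag = "zero_variance"))
      }
      tt <- t.test(xa, xb)
      tibble::tibble(log2fc = l2fc, statistic = unname(tt$statistic),
                     p.value = tt$p.value, flag = "ok")
    }) |>
    dplyr::ungroup()
  res$adj.p.value <- p.adjust(res$p.value, adjust)
  res$class <- dplyr::case_when(
    is.na(res$adj.p.value) ~ "ns",
    res$adj.p.value < alpha & res$log2fc > 0 ~ "up",
    res$adj.p.value < alpha & res$log2fc < 0 ~ "down",
    .default = "ns"
  )
  class(res) <- c("turnover_diff", class(res))
  res
}
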