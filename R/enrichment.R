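# Fisher-exact overrepresentation of protein sets against annotation terms,
# combined-score ranking, and set-overlap (Venn + Fisher) tests.

.check_terms <- function(terms) {
  if (is.data.frame(terms)) {
    if (!all(c("term", "gene") %in% names(terms))) {
      rlang::abort("A term tibble needs columns `term` and `gene`.")
    }
    terms <- split(terms$gene, terms$term)
  }
  if (!is.list(terms) || is.null(names(terms)) || any(!nzchar(names(terms)))) {
    rlang::abort("`terms` must be a named list of protein sets (or a tibble).")
  }
  lapply(terms, unique)
}

#' Fisher overrepresentation analysis
#'
#' One-sided Fisher exact test (hypergeometric upper tail) of a query protein
#' set against each annotation term, with the aggregated identified proteins
#' as the background. Terms with no background members are excluded with a
#' message. BH-FDR is computed across the tested terms.
#'
#' @param query Character vector of query proteins (must be a subset of
#'   `background`).
#' @param background Character vector: the reference universe.
#' @param terms Named list of protein sets (GMT-style, see [read_gmt()]) or a
#'   tibble with columns `term` and `gene`.
#' @param fdr_cutoff Significance threshold on the BH-FDR (default 0.05).
#' @return An enrichment tibble: `term`, `k` (query hits), `n` (query size),
#'   `K` (background hits), `N` (background size), `fold`, `p.value`, `fdr`,
#'   `significant`.
#' @export
#' @examples
#' fisher_ora(c("a", "b"), c("a", "b", "c", "d"),
#'            list(t1 = c("a", "b", "c")))
fisher_ora <- function(query, background, terms, fdr_cutoff = 0.05) {
  query <- unique(query); background <- unique(background)
  if (!all(query %in% background)) {
    rlang::abort("`query` must be a subset of `background`.")
  }
  terms <- .check_terms(terms)
  N <- length(background)
  n <- length(query)
  rows <- purrr::imap(terms, function(members, id) {
    K <- sum(members %in% background)
    k <- sum(members %in% query)
    tibble::tibble(term = id, k = k, n = n, K = K, N = N)
  })
  out <- dplyr::bind_rows(rows)
  empty <- out$K == 0
  if (any(empty)) {
    rlang::inform(sprintf(
      "Excluded %d term(s) with no background members.", sum(empty)))
    out <- out[!empty, , drop = FALSE]
  }
  if (nrow(out) == 0) return(dplyr::mutate(out, fold = numeric(0),
                                           p.value = numeric(0),
                                           fdr = numeric(0),
                                           significant = logical(0)))
  out$fold <- (out$k / out$n) / (out$K / out$N)
  out$p.value <- phyper(out$k - 1, out$K, out$N - out$K, out$n,
                        lower.tail = FALSE)
  out$fdr <- p.adjust(out$p.value, "BH")
  out$significant <- out$fdr < fdr_cutoff
  class(out) <- c("turnover_enrichment", class(out))
  out
}

#' Rank enriched terms by a combined FDR and fold-enrichment score
#'
#' Score = `(-log10 FDR) * log2(fold)`, descending; ties are broken by term
#' id for a stable order. The default `top_n = 4` mirrors reporting the top
#' four terms per cluster.
#'
#' @param rows Enrichment tibble from [fisher_ora()].
#' @param top_n Number of rows to return.
#' @return Ordered tibble with an added `score` column.
#' @export
rank_terms <- function(rows, top_n = 4) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    rlang::abort("`rows` must be a non-empty enrichment table.")
  }
  rows <- dplyr::mutate(
    tibble::as_tibble(rows),
    score = (-log10(.data$fdr)) * log2(.data$fold)
  )
  rows <- dplyr::arrange(rows, dplyr::desc(.data$score), .data$term)
  head(rows, top_n)
}

#' Overlap between two protein sets (Venn counts + Fisher test)
#'
#' Builds the 2x2 table {A&B, A only, B only, neither} over the universe and
#' tests association with a two-sided Fisher exact test. The odds ratio
#' reported is the sample (cross-product) odds ratio.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector: all considered proteins.
#' @return One-row tibble: `n_both`, `n_a_only`, `n_b_only`, `n_neither`,
#'   `odds_ratio`, `p.value`.
#' @export
#' @examples
#' overlap_test(letters[1:20], letters[11:20], letters)
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) rlang::abort("Empty universe.")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    rlang::abort("Both sets must be subsets of `universe`.")
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  tibble::tibble(
    n_both = tab[1, 1], n_a_only = tab[1, 2], n_b_only = tab[2, 1],
    n_neither = tab[2, 2], odds_ratio = or, p.value = p
  )
}

#' Read / write GMT annotation files
#'
#' GMT is tab-separated: term id, description, then member proteins. Duplicate
#' term ids are an error (the offending term is named).
#'
#' @param path File path.
#' @return `read_gmt()`: named list of character vectors with a `description`
#'   attribute per element dropped into `attr(x, "descriptions")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Malformed GMT line %d: need term, description, >=1 member.",
                         bad[1]))
  }
  ids <- vapply(parts, `[`, "", 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("Duplicate GMT term id: %s.", dup[1]))
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, "", 2), ids)
  sets
}

#' @rdname read_gmt
#' @param terms Named list of character vectors.
#' @param descriptions Optional named descriptions (defaults to the term id).
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  terms <- .check_terms(terms)
  desc <- descriptions %||% attr(terms, "descriptions") %||%
    setNames(names(terms), names(terms))
  lines <- vapply(names(terms), function(id) {
    paste(c(id, unname(desc[id]), terms[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
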