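# Readers and writers for the documented plain-text formats: PSM TSV, the
# spectra TSV dialect, reporter TSV, FA matrix CSV, FASTA and JSON run
# configs. Writers emit deterministic column order so outputs are
# byte-reproducible.

.read_tsv_checked <- function(path, required, col_types, kind) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  header <- names(suppressWarnings(
    readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                    progress = FALSE)))
  known <- col_types
  known$cols <- known$cols[intersect(names(col_types$cols), header)]
  out <- readr::read_tsv(path, col_types = known, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s file %s lacks required column(s): %s",
                         kind, path, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(out), names(col_types$cols))
  if (length(extra) > 0) {
    rlang::warn(sprintf("Ignoring unknown column(s) in %s: %s",
                        path, paste(extra, collapse = ", ")))
  }
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    rlang::abort(sprintf("Malformed %s row at line %d of %s.",
                         kind, prob$row[1] + 1L, path))
  }
  out
}

#' Read a PSM table (TSV)
#'
#' Required columns: `peptide`, `protein`, `charge`, `rt`. Optional:
#' `sequence`, `qvalue`, `modifications`, `pool`, `sample`,
#' `spectral_counts`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_psm_table <- function(path) {
  ct <- readr::cols(
    peptide = readr::col_character(), protein = readr::col_character(),
    charge = readr::col_integer(), rt = readr::col_double(),
    sequence = readr::col_character(), qvalue = readr::col_double(),
    modifications = readr::col_character(), pool = readr::col_character(),
    sample = readr::col_character(), spectral_counts = readr::col_integer()
  )
  .read_tsv_checked(path, c("peptide", "protein", "charge", "rt"), ct, "PSM")
}

#' Read centroid spectra from the TSV dialect
#'
#' Columns: `scan`, `rt` (seconds), `mz`, `intensity`; one row per centroid
#' peak. m/z must be positive and intensities non-negative.
#'
#' @param path TSV file path.
#' @return A tibble sorted by `rt` then `mz`.
#' @export
read_spectra <- function(path) {
  ct <- readr::cols(scan = readr::col_integer(), rt = readr::col_double(),
                    mz = readr::col_double(),
                    intensity = readr::col_double())
  out <- .read_tsv_checked(path, c("scan", "rt", "mz", "intensity"), ct,
                           "spectra")
  bad <- which(out$mz <= 0 | out$intensity < 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Invalid spectra row at line %d of %s.",
                         bad[1] + 1L, path))
  }
  dplyr::arrange(out, .data$rt, .data$mz)
}

#' Read a long reporter-intensity table (TSV)
#'
#' Columns: `psm_id`, `protein`, `pool`, `plex`, `channel`, `intensity`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_reporter_table <- function(path) {
  ct <- readr::cols(
    psm_id = readr::col_character(), protein = readr::col_character(),
    pool = readr::col_character(), plex = readr::col_character(),
    channel = readr::col_character(), intensity = readr::col_double()
  )
  .read_tsv_checked(path, c("protein", "plex", "channel", "intensity"), ct,
                    "reporter")
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Tibble with `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    rlang::abort("Reading FASTA requires the Biostrings package.")
  }
  seqs <- Biostrings::readAAStringSet(path)
  tibble::tibble(name = names(seqs), sequence = as.character(seqs))
}

#' Write / read a long FA table with sample metadata (CSV)
#'
#' The FA values and the sample metadata travel in one CSV: metadata columns
#' are joined on `sample` at write time and split off at read time.
#'
#' @param fa Long FA tibble (`protein`, `sample`, `fa`, ...).
#' @param meta Sample metadata tibble (`sample`, ...).
#' @param path CSV path.
#' @export
write_fa_matrix <- function(fa, meta, path) {
  out <- fa |>
    dplyr::left_join(meta, by = "sample") |>
    dplyr::arrange(.data$protein, .data$sample)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_fa_matrix
#' @return `read_fa_matrix()`: list with `fa` and `meta` tibbles.
#' @export
read_fa_matrix <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("protein", "sample", "fa")
  if (!all(req %in% names(out))) {
    rlang::abort(sprintf("FA matrix %s lacks column(s): %s", path,
                         paste(setdiff(req, names(out)), collapse = ", ")))
  }
  meta_cols <- setdiff(names(out), c("protein", "fa", "fa_adj",
                                     "ref_missing", "n_peptides"))
  list(
    fa = dplyr::select(out, dplyr::any_of(c("protein", "sample", "fa",
                                            "fa_adj", "n_peptides"))),
    meta = dplyr::distinct(dplyr::select(out, dplyr::all_of(meta_cols)))
  )
}

#' Run configuration round trip (JSON)
#'
#' A run config records input paths, stage parameters and the seeds of every
#' stochastic stage; [read_run_config()] validates that the seeds are present
#' so that reruns are reproducible.
#'
#' @param config Named list of parameters; must contain a `seeds` entry.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  if (is.null(config$seeds)) {
    rlang::abort("`config` must carry a `seeds` entry for every stochastic stage.")
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$seeds)) {
    rlang::abort(sprintf("Config %s lacks the `seeds` entry.", path))
  }
  cfg
}

#' Write a set of result tables to a directory
#'
#' Each element of `objects` is written as `<name>.csv` with deterministic
#' row and column order.
#'
#' @param objects Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_results <- function(objects, dir) {
  if (is.null(names(objects)) || any(!nzchar(names(objects)))) {
    rlang::abort("`objects` must be a fully named list.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(objects), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(objects[[nm]]), p)
    p
  }, "")
  invisible(paths)
}
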