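# MS1 quantification: extracted-ion chromatogram (XIC) reconstruction and
# non-negative least-squares deconvolution of observed envelopes into old/new
# label-pool fractions.

# exact two-column NNLS, vectorized over fits. Inputs are the sufficient
# statistics of each least-squares problem; with only two non-negative
# coefficients the KKT solution is the unconstrained solution when it is
# feasible, otherwise the better of the two single-column fits.
.nnls_two <- function(soo, snn, son, soy, sny) {
  det <- soo * snn - son^2
  a <- ifelse(det > 0, (snn * soy - son * sny) / det, NA_real_)
  b <- ifelse(det > 0, (soo * sny - son * soy) / det, NA_real_)
  neg <- is.na(a) | a < 0 | b < 0
  if (any(neg)) {
    a1 <- pmax(0, soy / soo)          # old-only fit
    b1 <- pmax(0, sny / snn)          # new-only fit
    # SSE difference (constant Syy omitted): pick the lower
    sse_a <- -2 * a1 * soy + a1^2 * soo
    sse_b <- -2 * b1 * sny + b1^2 * snn
    use_a <- sse_a <= sse_b
    a[neg] <- ifelse(use_a[neg], a1[neg], 0)
    b[neg] <- ifelse(use_a[neg], 0, b1[neg])
  }
  list(a = a, b = b)
}

# bin an envelope's lines onto an observed m/z grid: each line is assigned to
# the nearest grid point within ppm_tol, abundances summed per grid point.
.bin_to_grid <- function(mz_lines, abundance, grid, ppm_tol) {
  out <- numeric(length(grid))
  if (length(mz_lines) == 0) return(out)
  idx <- findInterval(mz_lines, grid)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(grid))
  d_lo <- abs(mz_lines - grid[lo])
  d_hi <- abs(mz_lines - grid[hi])
  near <- ifelse(d_lo <= d_hi, lo, hi)
  ppm <- abs(mz_lines - grid[near]) / grid[near] * 1e6
  ok <- ppm <= ppm_tol
  if (any(ok)) {
    s <- tapply(abundance[ok], near[ok], sum)
    out[as.integer(names(s))] <- as.numeric(s)
  }
  out
}

#' Bin a theoretical envelope onto an observed m/z grid
#'
#' @param env An `isotope_envelope`.
#' @param grid Numeric vector of observed m/z values (increasing).
#' @param ppm_tol Matching tolerance in ppm.
#' @return Numeric abundance vector aligned with `grid`.
#' @export
bin_envelope <- function(env, grid, ppm_tol = 10) {
  stopifnot(inherits(env, "isotope_envelope"))
  .bin_to_grid(env$mz, env$abundance, grid, ppm_tol)
}

#' Deconvolve an observed envelope into old/new pool fractions
#'
#' Fits the observed intensity vector as a non-negative combination
#' `a_old * env_old + a_new * env_new` by exact two-column non-negative least
#' squares and reports `w = a_old / (a_old + a_new)`, the total scale, and the
#' residual (RMSE of the fit divided by the root-mean-square of the
#' observation). Envelope pairs whose binned shapes are nearly collinear
#' (cosine similarity > 0.99) cannot be deconvolved reliably and are flagged
#' `"unresolvable"`.
#'
#' @param observed Non-negative intensity vector on an m/z grid.
#' @param env_old,env_new Either `isotope_envelope` objects (then `mz` must
#'   give the grid) or numeric abundance vectors already on the grid.
#' @param mz Optional m/z grid for binning envelope objects.
#' @param ppm_tol Binning tolerance in ppm.
#' @return One-row tibble with columns `w`, `scale`, `residual`, `flag`.
#' @export
#' @examples
#' comp <- peptide_composition("PEPTIDEK")
#' old <- isotope_envelope(comp, scheme_natural(), charge = 2)
#' new <- isotope_envelope(comp, scheme_n15(0.96), charge = 2)
#' grid <- sort(c(old$mz, new$mz))
#' obs <- 0.3 * bin_envelope(old, grid) + 0.7 * bin_envelope(new, grid)
#' fit_fraction(obs, old, new, mz = grid)
fit_fraction <- function(observed, env_old, env_new, mz = NULL, ppm_tol = 10) {
  if (!is.numeric(observed) || length(observed) == 0) {
    rlang::abort("`observed` must be a non-empty numeric vector.")
  }
  if (all(observed == 0)) rlang::abort("All-zero observation.")
  if (inherits(env_old, "isotope_envelope")) {
    if (is.null(mz)) rlang::abort("Provide `mz` to bin envelope objects.")
    xo <- bin_envelope(env_old, mz, ppm_tol)
    xn <- bin_envelope(env_new, mz, ppm_tol)
  } else {
    xo <- env_old; xn <- env_new
  }
  if (length(xo) != length(observed) || length(xn) != length(observed)) {
    rlang::abort("Envelope vectors and observation must share the grid.")
  }
  flag <- "ok"
  if (sum(xo > 0) < 2 || sum(xn > 0) < 2) flag <- "unresolvable"
  soo <- sum(xo^2); snn <- sum(xn^2); son <- sum(xo * xn)
  if (soo > 0 && snn > 0 && son / sqrt(soo * snn) > 0.99) flag <- "unresolvable"
  soy <- sum(xo * observed); sny <- sum(xn * observed)
  fit <- .nnls_two(soo, snn, son, soy, sny)
  a <- fit$a; b <- fit$b
  w <- if (a + b > 0) a / (a + b) else NA_real_
  resid <- observed - a * xo - b * xn
  residual <- sqrt(mean(resid^2)) / sqrt(mean(observed^2))
  tibble::tibble(w = w, scale = a + b, residual = residual, flag = flag)
}

#' Peptide fractional abundance from integrated areas
#'
#' `FA = I_old / (I_old + I_new)`; the old-pool share of the total signal.
#' Pairs with zero total are undefined and return `NA` with a warning.
#'
#' @param i_old,i_new Non-negative integrated areas (vectorized).
#' @return Numeric FA in `[0, 1]` (or `NA` where undefined).
#' @export
#' @examples
#' peptide_fa(8, 92)   # 0.08
peptide_fa <- function(i_old, i_new) {
  if (any(i_old < 0, na.rm = TRUE) || any(i_new < 0, na.rm = TRUE)) {
    rlang::abort("Areas must be non-negative.")
  }
  tot <- i_old + i_new
  undef <- !is.na(tot) & tot == 0
  if (any(undef)) {
    rlang::warn(sprintf("%d peptide(s) with zero total area flagged as NA.",
                        sum(undef)))
  }
  ifelse(tot > 0, i_old / tot, NA_real_)
}

#' Extract ion chromatogram areas for target m/z values
#'
#' For each target, sums the intensities of centroid peaks within `ppm_tol`
#' per scan and integrates the resulting chromatogram over retention time by
#' the trapezoidal rule (a single contributing scan contributes its intensity
#' at unit width).
#'
#' @param spectra Tibble of centroided MS1 peaks with columns `scan`, `rt`
#'   (seconds), `mz`, `intensity`.
#' @param targets Numeric vector of target m/z values, or a tibble with
#'   columns `target_id` and `mz`.
#' @param ppm_tol Matching tolerance in ppm (non-negative).
#' @param rt_range Optional `c(min, max)` retention-time window in seconds.
#' @return Tibble with `target_id`, `mz`, `area`, `n_scans`, `ppm_tol`.
#' @export
extract_xic <- function(spectra, targets, ppm_tol = 10, rt_range = NULL) {
  req <- c("scan", "rt", "mz", "intensity")
  if (!is.data.frame(spectra) || !all(req %in% names(spectra))) {
    rlang::abort("`spectra` needs columns scan, rt, mz, intensity.")
  }
  if (nrow(spectra) == 0) rlang::abort("Empty spectra table.")
  if (ppm_tol < 0) rlang::abort("`ppm_tol` must be non-negative.")
  if (is.numeric(targets)) {
    targets <- tibble::tibble(target_id = seq_along(targets), mz = targets)
  }
  if (!is.null(rt_range)) {
    spectra <- spectra[spectra$rt >= rt_range[1] & spectra$rt <= rt_range[2], ]
  }
  sp <- spectra[order(spectra$mz), ]
  res <- purrr::map(seq_len(nrow(targets)), function(i) {
    t_mz <- targets$mz[i]
    tol <- t_mz * ppm_tol / 1e6
    lo <- findInterval(t_mz - tol, sp$mz) + 1L
    hi <- findInterval(t_mz + tol, sp$mz)
    if (hi < lo) {
      return(tibble::tibble(target_id = targets$target_id[i], mz = t_mz,
                            area = 0, n_scans = 0L, ppm_tol = ppm_tol))
    }
    hits <- sp[lo:hi, ]
    per_scan <- hits |>
      dplyr::group_by(.data$scan, .data$rt) |>
      dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop") |>
      dplyr::arrange(.data$rt)
    area <- if (nrow(per_scan) == 1) {
      per_scan$intensity
    } else {
      sum(diff(per_scan$rt) *
            (head(per_scan$intensity, -1) + per_scan$intensity[-1]) / 2)
    }
    tibble::tibble(target_id = targets$target_id[i], mz = t_mz, area = area,
                   n_scans = nrow(per_scan), ppm_tol = ppm_tol)
  })
  dplyr::bind_rows(res)
}

#' Filter a PSM table by length, q-value and diGly status
#'
#' Applies the identification-level filters used before quantification:
#' minimum peptide length 5 and q-value at most 0.01 (protein-level FDR 1%);
#' `digly_only = TRUE` additionally retains only PSMs carrying the
#' +114.042927 ubiquitin-remnant modification (detected in the bracketed
#' sequence or a `modifications` column).
#'
#' @param psms Tibble with a `sequence` column; `qvalue` and `modifications`
#'   columns are used when present.
#' @param min_length Minimum residue count.
#' @param max_q Maximum q-value (ignored if no `qvalue` column).
#' @param digly_only Keep only diGly-modified rows.
#' @return The filtered tibble.
#' @export
#' @examples
#' psms <- tibble::tibble(sequence = c("ACDK", "ACDEK"), qvalue = c(0, 0))
#' filter_peptides(psms)   # drops the length-4 row
filter_peptides <- function(psms, min_length = 5, max_q = 0.01,
                            digly_only = FALSE) {
  if (!is.data.frame(psms) || !"sequence" %in% names(psms)) {
    rlang::abort("`psms` must have a `sequence` column.")
  }
  out <- tibble::as_tibble(psms)
  if (nrow(out) == 0) return(out)
  bare <- gsub("\\[[-0-9.]+\\]", "", out$sequence)
  out <- out[nchar(bare) >= min_length, , drop = FALSE]
  if ("qvalue" %in% names(out)) {
    out <- out[is.na(out$qvalue) | out$qvalue <= max_q, , drop = FALSE]
  }
  if (digly_only) {
    has_digly <- stringr::str_detect(out$sequence, stringr::fixed("114.042927"))
    if ("modifications" %in% names(out)) {
      has_digly <- has_digly |
        stringr::str_detect(tidyr::replace_na(out$modifications, ""),
                            stringr::fixed("114.042927"))
    }
    out <- out[has_digly, , drop = FALSE]
  }
  out
}

# envelope cache for quantify_ms1: keyed by sequence|charge|scheme
.envelope_pair <- function(cache, sequence, charge, label, enrichment, trunc,
                           mods) {
  key <- paste(sequence, charge, label, enrichment, trunc, sep = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  comp <- peptide_composition(sequence, mods)
  new_scheme <- if (label == "n15") {
    scheme_n15(enrichment)
  } else {
    n_k <- sum(strsplit(gsub("\\[[-0-9.]+\\]", "", sequence), "")[[1]] == "K")
    scheme_lys13c(n_k)
  }
  pair <- list(
    old = isotope_envelope(comp, scheme_natural(), charge, trunc),
    new = isotope_envelope(comp, new_scheme, charge, trunc)
  )
  cache[[key]] <- pair
  pair
}

#' Quantify peptide turnover from MS1 spectra
#'
#' For each PSM (unique peptide/charge), computes theoretical old-pool
#' (natural) and new-pool (labeled) isotopologue envelopes, reconstructs the
#' XIC area of every envelope line around the PSM's retention-time apex, and
#' deconvolves the areas into old/new contributions by non-negative least
#' squares. Because the theoretical envelopes are normalized, the fitted
#' coefficients are directly the integrated old and new areas. Charge states
#' are fitted independently and areas summed per peptide; unresolvable
#' charge states (nearly collinear envelope pair) are excluded from the
#' rollup.
#'
#' @param spectra Centroid peak tibble (`scan`, `rt`, `mz`, `intensity`) for
#'   one sample/run.
#' @param psms PSM tibble with columns `peptide`, `protein`, `charge`, `rt`
#'   (apex seconds). Extra columns are carried through.
#' @param label `"n15"` (SILAM) or `"lys13c"` (heavy-lysine pulse).
#' @param enrichment Per-atom 15N incorporation of the labeled pool.
#' @param ppm_tol XIC matching tolerance in ppm.
#' @param rt_halfwidth Half-width of the extraction window (seconds).
#' @param trunc Envelope truncation threshold.
#' @param mods Modification set applied to every peptide (default none).
#' @param aggregate_charges Sum areas across charge states per peptide.
#' @param envelope_cache Optional environment reused across calls so that
#'   theoretical envelopes are computed once per peptide/charge.
#' @return A peptide-turnover tibble: `peptide`, `protein`, (`charge`,)
#'   `i_old`, `i_new`, `fa`, `residual`, `flag`.
#' @export
quantify_ms1 <- function(spectra, psms, label = c("n15", "lys13c"),
                         enrichment = 0.96, ppm_tol = 10, rt_halfwidth = 30,
                         trunc = 1e-4, mods = NULL, aggregate_charges = TRUE,
                         envelope_cache = NULL) {
  label <- match.arg(label)
  req <- c("peptide", "protein", "charge", "rt")
  if (!all(req %in% names(psms))) {
    rlang::abort("`psms` needs columns peptide, protein, charge, rt.")
  }
  if (nrow(spectra) == 0) rlang::abort("Empty spectra table.")
  psms <- dplyr::distinct(tibble::as_tibble(psms),
                          .data$peptide, .data$charge, .keep_all = TRUE)

  cache <- envelope_cache %||% new.env(parent = emptyenv())
  # build the full target table: one row per (psm, pool, envelope line);
  # plain vectors accumulated and bound once (hot path)
  n_psm <- nrow(psms)
  acc <- vector("list", n_psm)
  for (i in seq_len(n_psm)) {
    pair <- .envelope_pair(cache, psms$peptide[i], psms$charge[i], label,
                           enrichment, trunc, mods)
    grid <- sort(c(pair$old$mz, pair$new$mz))
    # merge grid lines unresolvable at the matching tolerance
    grid <- grid[c(TRUE, diff(grid) / grid[-1] * 1e6 > ppm_tol)]
    acc[[i]] <- list(
      psm = rep.int(i, length(grid)), mz = grid,
      xo = .bin_to_grid(pair$old$mz, pair$old$abundance, grid, ppm_tol),
      xn = .bin_to_grid(pair$new$mz, pair$new$abundance, grid, ppm_tol)
    )
  }
  targets <- tibble::tibble(
    psm = unlist(lapply(acc, `[[`, "psm"), use.names = FALSE),
    mz = unlist(lapply(acc, `[[`, "mz"), use.names = FALSE),
    xo = unlist(lapply(acc, `[[`, "xo"), use.names = FALSE),
    xn = unlist(lapply(acc, `[[`, "xn"), use.names = FALSE)
  )
  targets$rt_apex <- psms$rt[targets$psm]

  ord <- order(spectra$mz)
  sp_mz <- spectra$mz[ord]
  sp_scan <- spectra$scan[ord]
  sp_rt <- spectra$rt[ord]
  sp_int <- spectra$intensity[ord]
  t_mz <- targets$mz
  tol <- t_mz * ppm_tol / 1e6
  lo <- findInterval(t_mz - tol, sp_mz) + 1L
  hi <- findInterval(t_mz + tol, sp_mz)
  n_hit <- pmax(hi - lo + 1L, 0L)
  t_idx <- rep.int(seq_along(t_mz), n_hit)
  row_idx <- unlist(purrr::map2(lo[n_hit > 0], hi[n_hit > 0], seq.int),
                    use.names = FALSE)
  area <- numeric(nrow(targets))
  if (length(row_idx) > 0) {
    # each observed peak contributes to its nearest target only
    d_ppm <- abs(sp_mz[row_idx] - t_mz[t_idx]) / t_mz[t_idx]
    keep1 <- order(row_idx, d_ppm)
    keep1 <- keep1[!duplicated(row_idx[keep1])]
    t_i <- t_idx[keep1]; r_i <- row_idx[keep1]
    in_rt <- abs(sp_rt[r_i] - targets$rt_apex[t_i]) <= rt_halfwidth
    t_i <- t_i[in_rt]; r_i <- r_i[in_rt]
    if (length(t_i) > 0) {
      # sum per (target, scan), then trapezoid over retention time
      scan_min <- min(sp_scan[r_i])
      key <- (t_i - 1) * (max(sp_scan[r_i]) - scan_min + 1L) +
        (sp_scan[r_i] - scan_min)
      o <- order(key)
      key_o <- key[o]
      first <- !duplicated(key_o)
      int_sum <- as.numeric(rowsum(sp_int[r_i][o], key_o, reorder = FALSE))
      tt <- t_i[o][first]
      rr <- sp_rt[r_i][o][first]
      # consecutive scans of the same target
      n <- length(tt)
      if (n > 0) {
        same <- tt[-n] == tt[-1]
        contrib <- diff(rr) * (int_sum[-n] + int_sum[-1]) / 2
        tr_area <- rowsum(contrib[same], tt[-n][same], reorder = FALSE)
        a_vec <- numeric(max(tt))
        a_vec[as.integer(rownames(tr_area))] <- tr_area[, 1]
        # single-scan targets: area = intensity at unit width
        cnt <- tabulate(tt, nbins = max(tt))
        singles <- which(cnt == 1)
        if (length(singles) > 0) {
          a_vec[singles] <- int_sum[match(singles, tt)]
        }
        area[seq_along(a_vec)] <- a_vec
      }
    }
  }
  targets$area <- area

  # per-psm sufficient statistics via rowsum (one pass)
  stats_m <- rowsum(
    cbind(targets$xo^2, targets$xn^2, targets$xo * targets$xn,
          targets$xo * targets$area, targets$xn * targets$area,
          targets$area^2, 1),
    targets$psm, reorder = TRUE
  )
  psm_ids <- as.integer(rownames(stats_m))
  soo <- stats_m[, 1]; snn <- stats_m[, 2]; son <- stats_m[, 3]
  soy <- stats_m[, 4]; sny <- stats_m[, 5]; syy <- stats_m[, 6]
  n_lines <- stats_m[, 7]
  fit <- .nnls_two(soo, snn, son, soy, sny)
  sse <- pmax(0, syy - 2 * fit$a * soy - 2 * fit$b * sny +
                fit$a^2 * soo + fit$b^2 * snn + 2 * fit$a * fit$b * son)
  cosine <- son / sqrt(soo * snn)
  out <- tibble::tibble(
    peptide = psms$peptide[psm_ids],
    protein = psms$protein[psm_ids],
    charge = psms$charge[psm_ids],
    i_old = unname(fit$a), i_new = unname(fit$b),
    residual = ifelse(syy > 0, sqrt(sse / syy), NA_real_),
    flag = dplyr::case_when(
      syy == 0 ~ "no_signal",
      cosine > 0.99 ~ "unresolvable",
      .default = "ok"
    )
  )
  if (aggregate_charges) {
    out <- out |>
      dplyr::filter(.data$flag == "ok") |>
      dplyr::group_by(.data$peptide, .data$protein) |>
      dplyr::summarise(
        i_old = sum(.data$i_old), i_new = sum(.data$i_new),
        residual = mean(.data$residual), flag = "ok", .groups = "drop"
      )
  }
  out$fa <- ifelse(out$i_old + out$i_new > 0,
                   out$i_old / (out$i_old + out$i_new), NA_real_)
  dplyr::relocate(out, "fa", .after = "i_new")
}
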