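# Split-pool TMT quantification. Reporter data are kept in long ("tidy")
# form: one row per PSM x channel, with columns psm_id, protein, plex,
# channel, intensity (and a pool tag when old/new matrices travel together).

.check_reporter <- function(m) {
  req <- c("protein", "plex", "channel", "intensity")
  if (!is.data.frame(m) || !all(req %in% names(m))) {
    rlang::abort("Reporter table needs columns protein, plex, channel, intensity.")
  }
  if (any(m$intensity < 0, na.rm = TRUE)) {
    rlang::abort("Reporter intensities must be non-negative.")
  }
  tibble::as_tibble(m)
}

#' Equalize reporter channel totals (loading normalization)
#'
#' Divides each channel's intensities by that channel's grand total within its
#' plex, then rescales by the mean of the original totals so magnitudes stay
#' comparable. After normalization all channel sums within a plex are equal.
#'
#' @param m Long reporter tibble (`protein`, `plex`, `channel`, `intensity`,
#'   plus any other columns).
#' @return The tibble with normalized intensities.
#' @export
normalize_total <- function(m) {
  m <- .check_reporter(m)
  totals <- m |>
    dplyr::group_by(.data$plex, .data$channel) |>
    dplyr::summarise(total = sum(.data$intensity, na.rm = TRUE),
                     .groups = "drop")
  if (any(totals$total == 0)) {
    bad <- totals[totals$total == 0, ]
    rlang::abort(sprintf("Channel(s) with zero total intensity: %s.",
                         paste(bad$plex, bad$channel, sep = "/",
                               collapse = ", ")))
  }
  totals <- totals |>
    dplyr::group_by(.data$plex) |>
    dplyr::mutate(factor = mean(.data$total) / .data$total) |>
    dplyr::ungroup()
  m |>
    dplyr::left_join(dplyr::select(totals, "plex", "channel", "factor"),
                     by = c("plex", "channel")) |>
    dplyr::mutate(intensity = .data$intensity * .data$factor) |>
    dplyr::select(!"factor")
}

#' Bridge-channel scale factors across plexes
#'
#' Computes one multiplicative factor per plex such that protein-level
#' aggregated bridge-channel intensities agree across plexes (reference =
#' first plex). The factor is the robust median of per-protein ratios over
#' proteins shared by every plex's bridge channel.
#'
#' @param m Long reporter tibble.
#' @param layout Plex layout tibble with columns `plex`, `channel`,
#'   `is_bridge` (exactly one bridge channel per plex).
#' @return Tibble with `plex` and `factor`.
#' @export
bridge_scale <- function(m, layout) {
  m <- .check_reporter(m)
  bridges <- layout[layout$is_bridge, c("plex", "channel")]
  if (any(duplicated(bridges$plex)) ||
      !all(unique(m$plex) %in% bridges$plex)) {
    rlang::abort("Layout must define exactly one bridge channel per plex.")
  }
  agg <- m |>
    dplyr::inner_join(bridges, by = c("plex", "channel")) |>
    dplyr::group_by(.data$plex, .data$protein) |>
    dplyr::summarise(total = sum(.data$intensity, na.rm = TRUE),
                     .groups = "drop")
  plexes <- unique(m$plex)
  if (length(plexes) == 1) {
    return(tibble::tibble(plex = plexes, factor = 1))
  }
  wide <- tidyr::pivot_wider(agg, names_from = "plex", values_from = "total")
  shared <- wide[complete.cases(wide), , drop = FALSE]
  if (nrow(shared) == 0) rlang::abort("No shared bridge proteins across plexes.")
  ref <- as.character(plexes[1])
  factors <- vapply(as.character(plexes), function(p) {
    stats::median(shared[[ref]] / shared[[p]])
  }, numeric(1))
  tibble::tibble(plex = plexes, factor = unname(factors))
}

#' Apply per-plex scale factors
#'
#' @param m Long reporter tibble.
#' @param factors Tibble from [bridge_scale()].
#' @return The tibble with scaled intensities.
#' @export
apply_bridge <- function(m, factors) {
  m <- .check_reporter(m)
  m |>
    dplyr::left_join(factors, by = "plex") |>
    dplyr::mutate(intensity = .data$intensity * .data$factor) |>
    dplyr::select(!"factor")
}

#' Per-protein, per-channel fractional abundance from split pools
#'
#' With the PSM pools separated before quantification, FA per protein and
#' channel is the old-pool intensity sum over the total:
#' `FA = sum(old) / (sum(old) + sum(new))`. Proteins absent from the old pool
#' but present in the new pool get FA = 0; proteins absent from both are
#' absent from the result.
#'
#' @param old,new Long reporter tibbles for the 14N (old) and 15N (new) PSM
#'   pools, already normalized/bridge-aligned.
#' @return Tibble with `protein`, `plex`, `channel`, `i_old`, `i_new`, `fa`.
#' @export
channel_fa <- function(old, new) {
  old <- .check_reporter(old); new <- .check_reporter(new)
  s_old <- old |>
    dplyr::group_by(.data$protein, .data$plex, .data$channel) |>
    dplyr::summarise(i_old = sum(.data$intensity, na.rm = TRUE),
                     .groups = "drop")
  s_new <- new |>
    dplyr::group_by(.data$protein, .data$plex, .data$channel) |>
    dplyr::summarise(i_new = sum(.data$intensity, na.rm = TRUE),
                     .groups = "drop")
  out <- dplyr::full_join(s_old, s_new,
                          by = c("protein", "plex", "channel")) |>
    dplyr::mutate(
      i_old = tidyr::replace_na(.data$i_old, 0),
      i_new = tidyr::replace_na(.data$i_new, 0),
      fa = ifelse(.data$i_old + .data$i_new > 0,
                  .data$i_old / (.data$i_old + .data$i_new), NA_real_)
    )
  if (any(is.na(out$fa))) rlang::abort("Protein absent from both pools.")
  out
}

#' Split-pool TMT FA pipeline
#'
#' Chains loading normalization, bridge alignment and [channel_fa()], then maps
#' channels to samples and drops bridge channels. By default loading factors
#' are derived from the *combined* old + new channel totals and applied to both
#' pools: the physical loading of a channel is the total material in it, and a
#' shared factor cancels in the FA ratio, so the planted FA signal is preserved
#' exactly while channel sums are still equalized. `normalize = "per_pool"`
#' instead equalizes each pool matrix separately (the literal reading of
#' per-channel-total division); `"none"` skips loading normalization.
#'
#' @param old,new Long reporter tibbles for the two PSM pools.
#' @param layout Tibble with `plex`, `channel`, `sample`, `is_bridge`.
#' @param normalize `"joint"` (default), `"per_pool"` or `"none"`.
#' @return FA tibble: `protein`, `sample`, `plex`, `channel`, `i_old`,
#'   `i_new`, `fa`.
#' @export
tmt_fa <- function(old, new, layout, normalize = c("joint", "per_pool", "none")) {
  normalize <- match.arg(normalize)
  old <- .check_reporter(old); new <- .check_reporter(new)
  if (normalize == "joint") {
    combined <- dplyr::bind_rows(
      dplyr::mutate(old, .pool = "old"),
      dplyr::mutate(new, .pool = "new")
    )
    combined <- normalize_total(combined)
    factors <- bridge_scale(combined, layout)
    combined <- apply_bridge(combined, factors)
    old <- dplyr::select(dplyr::filter(combined, .data$.pool == "old"), !".pool")
    new <- dplyr::select(dplyr::filter(combined, .data$.pool == "new"), !".pool")
  } else if (normalize == "per_pool") {
    old <- normalize_total(old); new <- normalize_total(new)
    f_old <- bridge_scale(old, layout); f_new <- bridge_scale(new, layout)
    old <- apply_bridge(old, f_old); new <- apply_bridge(new, f_new)
  }
  fa <- channel_fa(old, new)
  fa |>
    dplyr::inner_join(layout, by = c("plex", "channel")) |>
    dplyr::filter(!.data$is_bridge) |>
    dplyr::select("protein", "sample", "plex", "channel", "i_old", "i_new",
                  "fa")
}
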