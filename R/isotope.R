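# Isotopologue envelope machinery for peptides under natural, 15N-enriched and
# 13C6-lysine label schemes. Envelopes are binned by neutron-count shift from
# the monoisotopic species; each bin keeps its exact abundance-weighted mass.

#' Label schemes
#'
#' Constructors for the three labeling states a peptide species can be in:
#' `scheme_natural()` (all elements at natural abundance), `scheme_n15(p)`
#' (every nitrogen atom is 15N with probability `p`, emulating 15N-enriched
#' chow), and `scheme_lys13c(n_labeled)` (each labeled lysine contributes six
#' pure 13C atoms, i.e. a +6.020129 Da shift with six carbons removed from the
#' natural-carbon pool).
#'
#' @param p Per-atom 15N incorporation probability in `[0, 1]`.
#' @param n_labeled Number of 13C6-labeled lysines in the peptide.
#' @return A `label_scheme` object.
#' @export
#' @examples
#' scheme_natural()
#' scheme_n15(0.96)
#' scheme_lys13c(2)
scheme_natural <- function() {
  structure(list(variant = "natural"), class = "label_scheme")
}

#' @rdname scheme_natural
#' @export
scheme_n15 <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    rlang::abort("`p` must be a single value in [0, 1].")
  }
  structure(list(variant = "nitrogen15", p = p), class = "label_scheme")
}

#' @rdname scheme_natural
#' @export
scheme_lys13c <- function(n_labeled) {
  if (!is.numeric(n_labeled) || length(n_labeled) != 1 || is.na(n_labeled) ||
      n_labeled < 0 || n_labeled != round(n_labeled)) {
    rlang::abort("`n_labeled` must be a single non-negative integer.")
  }
  structure(list(variant = "lys13c", n_labeled = as.integer(n_labeled)),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  extra <- switch(x$variant,
    nitrogen15 = sprintf(" (p = %g)", x$p),
    lys13c = sprintf(" (%d labeled Lys)", x$n_labeled),
    ""
  )
  cat("<label_scheme> ", x$variant, extra, "\n", sep = "")
  invisible(x)
}

#' Elemental composition of a peptide
#'
#' Sums residue formulas plus terminal water plus modification contributions.
#' Modifications given in `mods` are applied by target: `"N-term"` targets are
#' applied once, residue-letter targets once per matching residue (static mods
#' with no matching residue contribute nothing). Bracketed mass deltas inside
#' the sequence (e.g. `"K[114.042927]"`, or a leading `"[229.1629]"` for an
#' N-terminal tag) are added as fixed mass offsets.
#'
#' @param sequence Amino-acid string using the 20 standard one-letter codes,
#'   optionally with bracketed mass deltas.
#' @param mods A modification tibble as returned by [builtin_modifications()],
#'   or `NULL` for none. Only rows with `type == "static"` are auto-applied.
#' @return An `elemental_composition`: counts of C/H/N/O/S for the neutral
#'   peptide, a fixed mass term for contributions outside the natural isotope
#'   pools, and the residue tally.
#' @export
#' @examples
#' peptide_composition("GG")                      # C4 H8 N2 O3
#' peptide_composition("PEPTIDE")
#' peptide_composition("ACDK", mods = builtin_modifications())
peptide_composition <- function(sequence, mods = NULL) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      !nzchar(sequence)) {
    rlang::abort("`sequence` must be a single non-empty string.")
  }
  # pull out bracketed deltas
  fixed <- 0
  deltas <- stringr::str_match_all(sequence, "\\[([-0-9.]+)\\]")[[1]]
  if (nrow(deltas) > 0) fixed <- fixed + sum(as.numeric(deltas[, 2]))
  bare <- gsub("\\[[-0-9.]+\\]", "", sequence)
  residues <- strsplit(bare, "")[[1]]
  unknown <- setdiff(residues, rownames(.aa_comp))
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown residue code(s): ",
                        paste(unique(unknown), collapse = ", ")))
  }
  res_tab <- table(factor(residues, levels = rownames(.aa_comp)))
  counts <- colSums(.aa_comp[residues, , drop = FALSE])
  counts[c("H", "O")] <- counts[c("H", "O")] + c(2, 1)  # terminal water

  if (!is.null(mods)) {
    req <- c("name", "target", "mass_shift", "type")
    if (!is.data.frame(mods) || !all(req %in% names(mods))) {
      rlang::abort("`mods` must have columns name, target, mass_shift, type.")
    }
    static <- mods[mods$type == "static", , drop = FALSE]
    for (i in seq_len(nrow(static))) {
      tgt <- static$target[i]
      n_app <- if (identical(tgt, "N-term")) {
        1L
      } else {
        sum(res_tab[strsplit(tgt, "")[[1]]], na.rm = TRUE)
      }
      if (n_app == 0) next
      mc <- .mod_comp[[static$name[i]]]
      if (is.null(mc)) {
        # unknown modification: pure mass delta
        fixed <- fixed + n_app * static$mass_shift[i]
      } else {
        counts <- counts + n_app * mc$counts[names(counts)]
        fixed <- fixed + n_app * mc$fixed
      }
    }
  }

  structure(
    list(counts = counts, fixed_mass = fixed,
         residues = res_tab, n_residues = length(residues)),
    class = "elemental_composition"
  )
}

#' Monoisotopic mass of a composition or envelope input
#'
#' @param comp An `elemental_composition`.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass(peptide_composition("PEPTIDE"))  # 799.35996
monoisotopic_mass <- function(comp) {
  stopifnot(inherits(comp, "elemental_composition"))
  sum(comp$counts * .mono_mass[names(comp$counts)]) + comp$fixed_mass
}

#' @export
print.elemental_composition <- function(x, ...) {
  f <- paste0(names(x$counts)[x$counts > 0], x$counts[x$counts > 0],
              collapse = "")
  cat("<elemental_composition> ", f,
      if (x$fixed_mass != 0) sprintf(" + %.6f Da fixed", x$fixed_mass),
      sprintf("  (mono %.5f Da, %d residues)\n",
              monoisotopic_mass(x), x$n_residues), sep = "")
  invisible(x)
}

# -- convolution core ---------------------------------------------------------

# (P, M) pair: P[j+1] = probability of neutron shift j, M[j+1] = sum over
# isotopologues in bin j of probability * total atomic mass. Convolution keeps
# both so each bin's exact expected mass is available at the end.
.pm_conv <- function(a, b, prune = 1e-15) {
  na <- length(a$P); nb <- length(b$P)
  P <- numeric(na + nb - 1)
  M <- numeric(na + nb - 1)
  for (i in seq_len(na)) {
    idx <- i:(i + nb - 1)
    P[idx] <- P[idx] + a$P[i] * b$P
    M[idx] <- M[idx] + a$M[i] * b$P + a$P[i] * b$M
  }
  keep <- max(which(P > prune), 1L)
  list(P = P[seq_len(keep)], M = M[seq_len(keep)])
}

# n-fold self-convolution by binary powering
.pm_power <- function(base, n, prune = 1e-15) {
  out <- list(P = 1, M = 0)  # identity: zero atoms
  while (n > 0) {
    if (n %% 2 == 1) out <- .pm_conv(out, base, prune)
    base <- if (n > 1) .pm_conv(base, base, prune) else base
    n <- n %/% 2
  }
  out
}

# single-atom (P, M) for an element, optionally with overridden abundances
.atom_pm <- function(element, abundance = NULL) {
  iso <- .isotopes()[[element]]
  ab <- abundance %||% iso$abundance
  width <- max(iso$shift) + 1L
  P <- numeric(width); M <- numeric(width)
  P[iso$shift + 1L] <- ab
  M[iso$shift + 1L] <- ab * iso$mass
  list(P = P, M = M)
}

#' Isotopologue envelope of a peptide composition
#'
#' Convolves per-element isotope distributions (binomial/multinomial in the
#' atom counts) into the isotopologue envelope of the neutral or charged
#' species, bins by neutron-count shift, truncates at `trunc` relative
#' abundance and renormalizes. Under `scheme_n15(p)` every nitrogen is 15N
#' with probability `p` and all other elements stay at natural abundance;
#' under `scheme_lys13c(n)` six carbons per labeled lysine leave the natural
#' carbon pool and contribute a fixed +6.020129 Da each.
#'
#' @param comp An `elemental_composition` from [peptide_composition()].
#' @param scheme A [label_scheme][scheme_natural] (default natural).
#' @param charge Charge state; `0` returns neutral masses, `z >= 1` returns
#'   m/z = (mass + z * proton) / z.
#' @param trunc Relative-abundance truncation threshold in (0, 1).
#' @return An `isotope_envelope` tibble with columns `mass` (neutral Da), `mz`
#'   and `abundance` (sums to 1), plus `charge` and `label` attributes.
#' @export
#' @examples
#' env <- isotope_envelope(peptide_composition("PEPTIDE"), charge = 2)
#' head(env)
isotope_envelope <- function(comp, scheme = scheme_natural(), charge = 1L,
                             trunc = 1e-6) {
  stopifnot(inherits(comp, "elemental_composition"))
  if (!inherits(scheme, "label_scheme")) {
    rlang::abort("`scheme` must be a label_scheme object.")
  }
  if (!is.numeric(charge) || length(charge) != 1 || charge < 0 ||
      charge != round(charge)) {
    rlang::abort("`charge` must be a non-negative integer (0 = neutral).")
  }
  if (!is.numeric(trunc) || length(trunc) != 1 || trunc <= 0 || trunc >= 1) {
    rlang::abort("`trunc` must lie strictly within (0, 1).")
  }

  counts <- comp$counts
  fixed <- comp$fixed_mass
  n_override <- NULL
  if (scheme$variant == "nitrogen15") {
    n_override <- c(1 - scheme$p, scheme$p)
  } else if (scheme$variant == "lys13c") {
    n_k <- as.integer(comp$residues["K"])
    if (is.na(n_k)) n_k <- 0L
    if (scheme$n_labeled > n_k) {
      rlang::abort(sprintf(
        "Scheme labels %d lysines but the sequence has only %d.",
        scheme$n_labeled, n_k))
    }
    n_c <- 6L * scheme$n_labeled
    if (counts["C"] < n_c) rlang::abort("Not enough carbon atoms for the label.")
    counts["C"] <- counts["C"] - n_c
    fixed <- fixed + n_c * .mono_mass["C"] + n_c * unname(mass_constants()["c13_delta"])
  }

  pm <- list(P = 1, M = 0)
  for (el in names(counts)) {
    n <- as.integer(counts[el])
    if (n == 0) next
    ab <- if (el == "N") n_override else NULL
    pm <- .pm_conv(pm, .pm_power(.atom_pm(el, ab), n))
  }

  P <- pm$P
  mass <- ifelse(P > 0, pm$M / P, NA_real_) + fixed
  keep <- which(P / sum(P) >= trunc & P > 0)
  P <- P[keep]; mass <- mass[keep]
  P <- P / sum(P)
  proton <- unname(mass_constants()["proton"])
  mz <- if (charge == 0) mass else (mass + charge * proton) / charge

  structure(
    tibble::tibble(mass = mass, mz = mz, abundance = P),
    class = c("isotope_envelope", class(tibble::tibble())),
    charge = as.integer(charge),
    label = scheme$variant
  )
}

#' Abundance-weighted mean mass of an envelope
#'
#' @param env An `isotope_envelope`.
#' @return Mean neutral mass in Da.
#' @export
#' @examples
#' envelope_mean_mass(isotope_envelope(peptide_composition("GG"), charge = 0))
envelope_mean_mass <- function(env) {
  stopifnot(inherits(env, "isotope_envelope"))
  if (nrow(env) == 0) rlang::abort("Empty envelope.")
  sum(env$mass * env$abundance) / sum(env$abundance)
}

#' Mix two envelopes of the same charge
#'
#' Pointwise `w * old + (1 - w) * new` on the union mass grid (lines closer
#' than 1e-9 Da are merged), renormalized. This is the theoretical shape of an
#' MS1 window containing both the old (pre-labeling) and new (labeled) species
#' of one peptide.
#'
#' @param w Old-pool weight in `[0, 1]`.
#' @param env_old,env_new `isotope_envelope`s with equal charge.
#' @return An `isotope_envelope` labeled `"mixture"`.
#' @export
#' @examples
#' comp <- peptide_composition("PEPTIDEK")
#' old <- isotope_envelope(comp, scheme_natural(), charge = 2)
#' new <- isotope_envelope(comp, scheme_n15(0.96), charge = 2)
#' mix_envelopes(0.3, old, new)
mix_envelopes <- function(w, env_old, env_new) {
  stopifnot(inherits(env_old, "isotope_envelope"),
            inherits(env_new, "isotope_envelope"))
  if (!is.numeric(w) || length(w) != 1 || w < 0 || w > 1) {
    rlang::abort("`w` must be a single value in [0, 1].")
  }
  if (!identical(attr(env_old, "charge"), attr(env_new, "charge"))) {
    rlang::abort("Envelope charge states differ.")
  }
  df <- dplyr::bind_rows(
    tibble::tibble(mass = env_old$mass, mz = env_old$mz,
                   abundance = w * env_old$abundance),
    tibble::tibble(mass = env_new$mass, mz = env_new$mz,
                   abundance = (1 - w) * env_new$abundance)
  )
  df <- df[df$abundance > 0, , drop = FALSE]
  df <- df[order(df$mz), ]
  # merge lines closer than 1e-9 Da; singleton lines keep their exact values
  grp <- cumsum(c(TRUE, diff(df$mz) > 1e-9))
  sizes <- tabulate(grp)
  if (any(sizes > 1)) {
    out <- df |>
      dplyr::mutate(.grp = grp) |>
      dplyr::group_by(.data$.grp) |>
      dplyr::summarise(
        mass = if (dplyr::n() == 1) .data$mass else
          sum(.data$mass * .data$abundance) / sum(.data$abundance),
        mz = if (dplyr::n() == 1) .data$mz else
          sum(.data$mz * .data$abundance) / sum(.data$abundance),
        abundance = sum(.data$abundance),
        .groups = "drop"
      ) |>
      dplyr::select(!".grp")
  } else {
    out <- tibble::as_tibble(df)
  }
  out$abundance <- out$abundance / sum(out$abundance)
  structure(out,
            class = c("isotope_envelope", class(tibble::tibble())),
            charge = attr(env_old, "charge"),
            label = "mixture")
}
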