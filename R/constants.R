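# Physical constants shared by the envelope code and every oracle/test:
# a single embedded isotope table so that no two code paths disagree on masses.

#' Stable-isotope masses and natural abundances
#'
#' The embedded isotope table used by all envelope computations. Masses are
#' monoisotopic atomic masses in Da; abundances are natural fractional
#' abundances (IUPAC-style values). `shift` is the neutron-count offset from
#' the lightest isotope, which indexes isotopologue bins.
#'
#' @return A tibble with columns `element`, `shift`, `mass`, `abundance`.
#' @export
#' @examples
#' isotope_table()
isotope_table <- function() {
  tibble::tribble(
    ~element, ~shift, ~mass,        ~abundance,
    "C", 0L, 12.0000000,    0.9893,
    "C", 1L, 13.0033548378, 0.0107,
    "H", 0L, 1.0078250319,  0.999885,
    "H", 1L, 2.0141017780,  0.000115,
    "N", 0L, 14.0030740052, 0.99636,
    "N", 1L, 15.0001088984, 0.00364,
    "O", 0L, 15.9949146221, 0.99757,
    "O", 1L, 16.9991315,    0.00038,
    "O", 2L, 17.9991604,    0.00205,
    "S", 0L, 31.97207069,   0.9499,
    "S", 1L, 32.97145850,   0.0075,
    "S", 2L, 33.96786683,   0.0425,
    "S", 4L, 35.96708088,   0.0001
  )
}

# per-element list form used internally: list(C = list(shift=, mass=, abundance=), ...)
.isotopes <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t0 <- isotope_table()
      tab <<- lapply(split(t0, t0$element), function(d) {
        list(shift = d$shift, mass = d$mass, abundance = d$abundance)
      })
    }
    tab
  }
})

# monoisotopic (lightest-isotope) element masses
.mono_mass <- c(
  C = 12.0000000, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, S = 31.97207069
)

#' Mass constants used throughout
#'
#' @format Named numeric constants:
#' * `proton`: proton mass used for m/z conversion (1.007276 Da)
#' * `n15_delta`: mass difference between 15N and 14N (0.9970349 Da)
#' * `c13_delta`: mass difference between 13C and 12C (1.0033548 Da)
#' * `water`: monoisotopic mass of H2O
#' @export
#' @examples
#' mass_constants()["proton"]
mass_constants <- function() {
  c(
    proton    = 1.007276,
    n15_delta = 14.0030740052 * -1 + 15.0001088984,
    c13_delta = 13.0033548378 - 12,
    water     = 2 * 1.0078250319 + 15.9949146221
  )
}

# residue elemental compositions (C, H, N, O, S) for the 20 standard amino acids,
# as residues (i.e. minus water)
.aa_comp <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

#' Built-in peptide modifications
#'
#' The modification set used in the quantification workflow: static
#' carbamidomethylation of cysteine (+57.02146), static TMT on lysine and the
#' peptide N-terminus (+229.1629), and the differential diGly ubiquitin remnant
#' (+114.042927) on C/K/S/T. Carbamidomethyl and TMT carry full elemental
#' compositions so the isotope envelope shape is correct for labeled peptides
#' (the TMT reagent's four 13C and one 15N are a fixed mass offset, not part of
#' the natural-isotope pools); diGly is applied as a pure mass delta.
#'
#' @return A tibble with columns `name`, `target` (residue letters or
#'   `"N-term"`), `mass_shift` (Da), `type` (`"static"` or `"differential"`).
#' @export
#' @examples
#' builtin_modifications()
builtin_modifications <- function() {
  tibble::tribble(
    ~name,              ~target,  ~mass_shift, ~type,
    "carbamidomethyl",  "C",      57.02146,    "static",
    "tmt10",            "K",      229.1629,    "static",
    "tmt10",            "N-term", 229.1629,    "static",
    "digly",            "CKST",   114.042927,  "differential"
  )
}

# elemental composition contributed per application of a built-in modification;
# `fixed` is mass outside the natural-isotope pools (heavy reagent atoms, or the
# remainder that makes the nominal mass shift exact).
.mod_comp <- list(
  # carbamidomethyl: C2H3NO; tiny remainder keeps the 57.02146 book value exact
  carbamidomethyl = list(counts = c(C = 2, H = 3, N = 1, O = 1, S = 0),
                         fixed = NA_real_),
  # TMT 10/11-plex tag: C8 H20 N O2 plus 4x13C + 1x15N as fixed mass
  tmt10 = list(counts = c(C = 8, H = 20, N = 1, O = 2, S = 0),
               fixed = NA_real_),
  # diGly remnant: pure mass delta (composition ignored for envelope shape)
  digly = list(counts = c(C = 0, H = 0, N = 0, O = 0, S = 0),
               fixed = NA_real_)
)
# fill `fixed` so that counts + fixed reproduces the book mass shift exactly
.mod_comp <- local({
  book <- c(carbamidomethyl = 57.02146, tmt10 = 229.1629, digly = 114.042927)
  for (nm in names(.mod_comp)) {
    comp_mass <- sum(.mod_comp[[nm]]$counts * .mono_mass[names(.mod_comp[[nm]]$counts)])
    .mod_comp[[nm]]$fixed <- unname(book[nm] - comp_mass)
  }
  .mod_comp
})
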