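# Elemental composition and isotopologue envelope math.

test_that("composition sums residues, water and modifications", {
  gg <- peptide_composition("GG")
  expect_equal(unname(gg$counts[c("C", "H", "N", "O", "S")]),
               c(4, 8, 2, 3, 0))

  expect_equal(monoisotopic_mass(peptide_composition("PEPTIDE")),
               799.35996, tolerance = 1e-7)

  mods <- builtin_modifications()
  cam <- mods[mods$name == "carbamidomethyl", ]
  for (seqn in c("ACDEF", "CCGCK")) {
    n_c <- sum(strsplit(seqn, "")[[1]] == "C")
    expect_equal(
      monoisotopic_mass(peptide_composition(seqn, cam)) -
        monoisotopic_mass(peptide_composition(seqn)),
      n_c * 57.02146, tolerance = 1e-9
    )
  }
  tmt <- mods[mods$name == "tmt10", ]
  for (seqn in c("ACDEK", "KGGKR")) {
    n_k <- sum(strsplit(seqn, "")[[1]] == "K")
    expect_equal(
      monoisotopic_mass(peptide_composition(seqn, tmt)) -
        monoisotopic_mass(peptide_composition(seqn)),
      (n_k + 1) * 229.1629, tolerance = 1e-9
    )
  }
  # bracketed deltas are fixed-mass offsets
  expect_equal(
    monoisotopic_mass(peptide_composition("GGK[114.042927]R")) -
      monoisotopic_mass(peptide_composition("GGKR")),
    114.042927
  )
  expect_error(peptide_composition("GGX"), "Unknown residue")
  # N count at least one nitrogen per residue
  for (seqn in c("PEPTIDE", "GAVLIK", "WRH")) {
    comp <- peptide_composition(seqn)
    expect_gte(comp$counts[["N"]], comp$n_residues)
  }
})

test_that("envelope matches brute-force isotopologue enumeration", {
  for (seqn in oracle_peptide_panel(12, seed = 42)) {
    env <- isotope_envelope(peptide_composition(seqn), charge = 0,
                            trunc = 1e-6)
    ora <- oracle_envelope(seqn, trunc = 1e-6)
    expect_equal(nrow(env), nrow(ora))
    expect_lt(max(abs(env$abundance - ora$prob)), 1e-10)
    expect_lt(max(abs(env$mass - ora$mass)), 1e-9)
  }
  # and under 15N enrichment
  env <- isotope_envelope(peptide_composition("PATK"), scheme_n15(0.7),
                          charge = 0, trunc = 1e-8)
  ora <- oracle_envelope("PATK", "nitrogen15", p15 = 0.7, trunc = 1e-8)
  expect_lt(max(abs(env$abundance - ora$prob)), 1e-10)
})

test_that("envelopes normalize, increase in mass and respect m/z conversion", {
  comp <- peptide_composition("PEPTIDEK")
  for (scheme in list(scheme_natural(), scheme_n15(0.5), scheme_n15(0.96),
                      scheme_lys13c(1))) {
    for (z in c(1, 2, 3)) {
      env <- isotope_envelope(comp, scheme, charge = z)
      expect_equal(sum(env$abundance), 1, tolerance = 1e-9)
      expect_true(all(diff(env$mass) > 0))
      expect_equal(env$mz, (env$mass + z * 1.007276) / z, tolerance = 1e-12)
    }
  }
  expect_error(isotope_envelope(comp, trunc = 0), "trunc")
  expect_error(isotope_envelope(comp, charge = -1), "charge")
})

test_that("degenerate 15N enrichment reproduces the natural envelope", {
  comp <- peptide_composition("ILYQK")
  nat <- isotope_envelope(comp, scheme_natural(), charge = 2)
  deg <- isotope_envelope(comp, scheme_n15(0.00364), charge = 2)
  expect_lt(max(abs(nat$abundance - deg$abundance)), 1e-12)
  expect_lt(max(abs(nat$mz - deg$mz)), 1e-12)
})

test_that("full 15N labeling shifts the nitrogen-free envelope by n_N x delta", {
  comp <- peptide_composition("PEPTIDEK")
  n_n <- comp$counts[["N"]]
  nat <- isotope_envelope(comp, scheme_natural(), charge = 0)
  full <- isotope_envelope(comp, scheme_n15(1), charge = 0)
  expect_equal(full$mass[1] - nat$mass[1], n_n * 0.9970349, tolerance = 1e-6)
})

test_that("13C6-lysine label adds 6.020129 Da per labeled lysine", {
  comp <- peptide_composition("GAVLYKPK")
  nat <- isotope_envelope(comp, charge = 0)
  for (nk in 1:2) {
    heavy <- isotope_envelope(comp, scheme_lys13c(nk), charge = 0)
    expect_equal(heavy$mass[1] - nat$mass[1], nk * 6.020129,
                 tolerance = 1e-5)
  }
  expect_error(isotope_envelope(comp, scheme_lys13c(3)), "lysines")
})

test_that("mean mass is linear in 15N enrichment", {
  comp <- peptide_composition("MQIFVK")
  n_n <- comp$counts[["N"]]
  base <- envelope_mean_mass(isotope_envelope(comp, charge = 0,
                                              trunc = 1e-12))
  for (p in c(0.2, 0.5, 0.9)) {
    m <- envelope_mean_mass(isotope_envelope(comp, scheme_n15(p), charge = 0,
                                             trunc = 1e-12))
    expect_equal(m - base, n_n * 0.9970349 * (p - 0.00364),
                 tolerance = 1e-6)
  }
})

test_that("mean mass handles degenerate envelopes", {
  one <- structure(tibble::tibble(mass = 500, mz = 501, abundance = 1),
                   class = c("isotope_envelope", class(tibble::tibble())),
                   charge = 1L, label = "natural")
  expect_equal(envelope_mean_mass(one), 500)
  two <- one
  two <- structure(tibble::tibble(mass = c(500, 501), mz = c(501, 502),
                                  abundance = c(0.5, 0.5)),
                   class = class(one), charge = 1L, label = "natural")
  expect_equal(envelope_mean_mass(two), 500.5)
})

test_that("mixing envelopes is a normalized pointwise combination", {
  comp <- peptide_composition("PEPTIDEK")
  old <- isotope_envelope(comp, scheme_natural(), charge = 2)
  new <- isotope_envelope(comp, scheme_n15(0.96), charge = 2)
  expect_equal(mix_envelopes(1, old, new)$abundance, old$abundance,
               tolerance = 1e-12)
  expect_equal(mix_envelopes(0, old, new)$abundance, new$abundance,
               tolerance = 1e-12)
  half <- mix_envelopes(0.5, old, new)
  expect_equal(sum(half$abundance), 1, tolerance = 1e-12)
  # disjoint grids: both shapes present at half area
  i_old <- half$mz %in% old$mz
  expect_equal(sum(half$abundance[i_old]), 0.5, tolerance = 1e-9)
  new3 <- isotope_envelope(comp, scheme_n15(0.96), charge = 3)
  expect_error(mix_envelopes(0.5, old, new3), "charge")
})
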