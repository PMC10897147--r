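# Ground-truth kinetics and the simulated datasets.

test_that("kinetic truth follows the closed form with a long-lived fraction", {
  des <- cohort_design(seed = 1)
  pan <- protein_panel(250, seed = 1)
  # closed-form check: k = 0.3 / month, lambda = 0, T = 3 months
  pan$k0[1] <- 0.3; pan$lambda[1] <- 0; pan$amp[1] <- 0
  # k very large -> FA -> lambda; k = 0 -> FA = 1
  pan$k0[2] <- 500; pan$lambda[2] <- 0.1; pan$amp[2] <- 0
  pan$k0[3] <- 0; pan$lambda[3] <- 0
  tr <- simulate_truth(des, pan)
  t1 <- tr$truth[tr$truth$protein == pan$protein[1], ]
  expect_equal(t1$fa_true, rep(exp(-0.9), nrow(t1)), tolerance = 1e-9)
  expect_equal(exp(-0.9), 0.40657, tolerance = 1e-5)
  t2 <- tr$truth[tr$truth$protein == pan$protein[2], ]
  expect_equal(t2$fa_true, rep(0.1, nrow(t2)), tolerance = 1e-6)
  t3 <- tr$truth[tr$truth$protein == pan$protein[3], ]
  expect_equal(t3$fa_true, rep(1, nrow(t3)))
  expect_true(all(tr$truth$fa_true >= 0 & tr$truth$fa_true <= 1))
  expect_true(all(tr$sample_truth$fa_sample >= 0 &
                    tr$sample_truth$fa_sample <= 1))
})

test_that("female profiles equal male profiles evaluated 9 months earlier", {
  des <- cohort_design(seed = 2)
  pan <- protein_panel(250, seed = 2)
  tr <- simulate_truth(des, pan)
  # compare on the underlying rate curve: female k at window mid m equals
  # male k at m - 9 by construction
  p <- pan[17, ]
  k_f <- turnoverFA:::.k_at_age(p$k0, 16.5 - 9, p$center, p$amp, p$width)
  f_row <- tr$truth[tr$truth$protein == p$protein &
                      tr$truth$sex == "female" & tr$truth$age == 18, ]
  expect_equal(f_row$k, k_f, tolerance = 1e-12)
  m_shift <- p$lambda + (1 - p$lambda) * exp(-k_f * 3)
  expect_equal(f_row$fa_true, m_shift, tolerance = 1e-12)
})

test_that("cohort sample table honors replicate overrides", {
  s <- cohort_samples(cohort_design(seed = 3))
  counts <- dplyr::count(s, .data$sex, .data$age)
  expect_equal(counts$n[counts$sex == "male"], rep(4, 5))
  f <- counts[counts$sex == "female", ]
  expect_equal(f$n[f$age %in% c(15, 24)], c(3, 3))
  expect_equal(f$n[!f$age %in% c(15, 24)], rep(4, 3))
})

test_that("simulated spectra are valid and deterministic given the seed", {
  des <- cohort_design(windows = cbind(9, 12), sexes = "male", seed = 5)
  pan <- protein_panel(240, seed = 5)[1:25, ]
  tr <- simulate_truth(des, pan)
  s1 <- simulate_ms1_sample(tr, "M12_r1", noise_cv = 0.1, seed = 77)
  s2 <- simulate_ms1_sample(tr, "M12_r1", layout = s1$layout, noise_cv = 0.1,
                            seed = 77)
  expect_identical(s1$spectra, s2$spectra)
  expect_true(all(s1$spectra$intensity >= 0))
  expect_true(all(s1$spectra$mz > 0))
  expect_error(simulate_ms1_sample(tr, "nope", layout = s1$layout), "Unknown")

  # proteins without peptides vanish downstream
  pan2 <- pan
  pan2$peptides[[1]] <- pan2$peptides[[1]][0, ]
  tr2 <- simulate_truth(des, pan2)
  res <- ms1_pipeline_fa(tr2, samples = "M12_r1", noise_cv = 0, seed = 1)
  expect_false(pan2$protein[1] %in% res$protein)
  expect_true(all(pan2$protein[-1] %in% res$protein))
})

test_that("TMT simulation respects the layout and duplicated plexes give unit factors", {
  pan <- protein_panel(240, seed = 6)
  tr <- simulate_truth(cohort_design(seed = 6), pan)
  sim <- simulate_tmt_dataset(tr, seed = 7)
  expect_true(all(sim$old$intensity >= 0))
  per_plex <- dplyr::count(dplyr::distinct(sim$layout, plex, channel), plex)
  expect_true(all(per_plex$n <= 10))
  expect_equal(sum(sim$layout$is_bridge), length(unique(sim$layout$plex)))

  # two byte-identical plexes: bridge factors exactly 1
  m1 <- sim$old[sim$old$plex == "m1", ]
  m2 <- dplyr::mutate(m1, plex = "m2")
  lay <- dplyr::bind_rows(
    dplyr::filter(sim$layout, plex == "m1"),
    dplyr::mutate(dplyr::filter(sim$layout, plex == "m1"), plex = "m2")
  )
  f <- bridge_scale(dplyr::bind_rows(m1, m2), lay)
  expect_equal(f$factor, c(1, 1))

  expect_error(
    simulate_tmt_dataset(tr, layout = dplyr::filter(sim$layout, !is_bridge)),
    "bridge")
})

test_that("inhibition truth follows the closed form and shifts the FA up", {
  inh <- simulate_inhibition(factor = 0.5, duration = 7, seed = 10)
  # a subunit with k = 0.1/day: treated FA e^{-0.35}, control e^{-0.7}
  tr <- inh$truth
  tr_t <- tr[tr$arm == "marizomib" & tr$protein %in% inh$subunits, ]
  tr_c <- tr[tr$arm == "vehicle" & tr$protein %in% inh$subunits, ]
  expect_equal(tr_t$fa_true, exp(-tr_c$k_eff * 0.5 * 7), tolerance = 1e-12)
  expect_true(all(tr_t$fa_true > tr_c$fa_true))
  expect_equal(median(tr_t$fa_true), exp(-0.35), tolerance = 0.15)
  expect_equal(median(tr_c$fa_true), exp(-0.7), tolerance = 0.2)
  # factor 1: arms identical in truth
  inh1 <- simulate_inhibition(factor = 1, seed = 10)
  w <- tidyr::pivot_wider(inh1$truth[, c("protein", "arm", "fa_true")],
                          names_from = "arm", values_from = "fa_true")
  expect_equal(w$marizomib, w$vehicle)
  expect_error(simulate_inhibition(factor = 0), "factor")
})

test_that("the inhibition round trip flags substrates as accumulating", {
  inh <- simulate_inhibition(seed = 20)
  da <- diff_abundance(inh$abundance, inh$arms, "marizomib", "vehicle")
  planted <- da$class[da$protein %in% inh$substrates]
  expect_gte(mean(planted == "up"), 0.9)
  bkg <- da$class[grepl("^Bkg", da$protein)]
  expect_lte(mean(bkg != "ns"), 0.02)
})

test_that("annotation fixture covers planted clusters and round-trips", {
  pan <- protein_panel(240, seed = 11)
  terms <- annotation_fixture(pan, seed = 12)
  for (comp in unique(pan$compartment)) {
    expect_true(all(pan$protein[pan$compartment == comp] %in% terms[[comp]]))
  }
  expect_equal(sum(grepl("^decoy", names(terms))), 20)
  tmp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(terms, tmp)
  expect_equal(read_gmt(tmp), terms, ignore_attr = TRUE)
})
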