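# Synthetic cohort with known turnover kinetics: ground-truth FA from a
# first-order model with a long-lived fraction, plus simulated MS1 and TMT
# datasets carrying the statistical structure the analysis assumes.

#' Cohort design: labeling windows, sexes, replicates
#'
#' Defaults emulate the study layout: five 3-month 15N labeling windows
#' (9-12, 12-15, 15-18, 18-21, 21-24 months; groups labeled by the end
#' month), two sexes with the female turnover profile shifted 9 months later,
#' and 4 replicates per group except 3 for the female 15 M and 24 M groups.
#'
#' @param windows Two-column matrix/list of window start/end months.
#' @param sexes Character vector of sexes.
#' @param replicates Replicates per group.
#' @param rep_overrides Tibble (`sex`, `age`, `replicates`) of exceptions.
#' @param sex_shift Months by which the female profile lags the male one.
#' @param seed Integer seed owned by the design.
#' @return A `cohort_design`.
#' @export
cohort_design <- function(windows = cbind(c(9, 12, 15, 18, 21),
                                          c(12, 15, 18, 21, 24)),
                          sexes = c("male", "female"),
                          replicates = 4,
                          rep_overrides = tibble::tibble(
                            sex = c("female", "female"),
                            age = c(15, 24), replicates = c(3, 3)),
                          sex_shift = 9,
                          seed = 1L) {
  windows <- as.matrix(windows)
  if (ncol(windows) != 2 || any(windows[, 2] <= windows[, 1])) {
    rlang::abort("`windows` must be start/end month pairs with end > start.")
  }
  if (replicates < 3) rlang::abort("Need at least 3 replicates per group.")
  structure(
    list(
      windows = tibble::tibble(
        window = seq_len(nrow(windows)),
        start = windows[, 1], end = windows[, 2],
        age = windows[, 2], mid = rowMeans(windows),
        duration = windows[, 2] - windows[, 1]
      ),
      sexes = sexes, replicates = replicates,
      rep_overrides = rep_overrides, sex_shift = sex_shift,
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' Sample table of a cohort design
#'
#' @param design A [cohort_design()].
#' @return Tibble: `sample`, `sex`, `age`, `window`, `replicate`.
#' @export
cohort_samples <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  grid <- tidyr::expand_grid(sex = design$sexes,
                             design$windows[, c("window", "age")])
  grid <- grid |>
    dplyr::left_join(design$rep_overrides, by = c("sex", "age")) |>
    dplyr::mutate(replicates = dplyr::coalesce(.data$replicates,
                                               design$replicates))
  grid |>
    dplyr::rowwise() |>
    dplyr::reframe(sex = .data$sex, age = .data$age, window = .data$window,
                   replicate = seq_len(.data$replicates)) |>
    dplyr::mutate(sample = sprintf("%s%02d_r%d", toupper(substr(.data$sex, 1, 1)),
                                   .data$age, .data$replicate),
                  .before = 1)
}

# deterministic tryptic-like peptide sequences: internal residues without K/R,
# C-terminal K or R
.random_peptides <- function(n) {
  inner <- c("G", "A", "S", "P", "V", "T", "L", "I", "N", "D", "Q", "E", "M",
             "H", "F", "Y", "W", "C")
  lens <- sample(8:16, n, replace = TRUE)
  vapply(lens, function(l) {
    paste0(paste(sample(inner, l - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, "")
}

#' Synthetic protein panel with planted trend archetypes
#'
#' Generates `n_proteins` proteins: the 34 proteasome subunit genes (19S and
#' 20S, with complex-specific base degradation rates so the 19S particle has
#' the higher FA) plus generic proteins. Every protein is assigned one of
#' `n_clusters` age-modulation archetypes (a Gaussian dip of the degradation
#' rate centered on a cluster-specific age, producing an FA bump there), a
#' compartment annotation tied to its archetype, insoluble/ubiquitinated
#' flags, and a panel of 3-8 tryptic peptides at charge 2-3.
#'
#' @param n_proteins Total panel size.
#' @param n_clusters Number of planted archetypes.
#' @param seed Integer seed.
#' @param prop_insoluble Fraction flagged insoluble.
#' @param k0_mean Median base degradation rate (per month) of generic
#'   proteins.
#' @param archetype_amp Fractional depth of the rate dip (0-1).
#' @param archetype_width Gaussian width of the dip (months).
#' @return Tibble: `protein`, `k0`, `lambda`, `archetype`, `center`,
#'   `compartment`, `insoluble`, `ubiquitinated`, `complex`, `peptides`
#'   (list of tibbles with `peptide`, `charge`).
#' @export
protein_panel <- function(n_proteins = 500, n_clusters = 5, seed = 1L,
                          prop_insoluble = 0.1, k0_mean = 0.25,
                          archetype_amp = 0.6, archetype_width = 2.5) {
  set.seed(seed)
  cx <- proteasome_complexes()
  n_px <- nrow(cx)
  if (n_proteins < n_px + n_clusters * 40) {
    rlang::abort("Panel too small for the proteasome set plus >= 40 proteins per archetype.")
  }
  ids <- c(cx$gene, sprintf("Prot%04d", seq_len(n_proteins - n_px)))
  complex <- c(cx$complex, rep(NA_character_, n_proteins - n_px))
  # base rates: generic lognormal around k0_mean, complex-specific for the
  # proteasome so 19S FA sits above 20S FA at every age
  k0 <- k0_mean * rlnorm(n_proteins, 0, 0.3)
  k0[complex %in% "20S"] <- 0.35 * rlnorm(sum(complex %in% "20S"), 0, 0.08)
  k0[complex %in% "19S"] <- 0.16 * rlnorm(sum(complex %in% "19S"), 0, 0.08)
  archetype <- sample(rep_len(seq_len(n_clusters), n_proteins))
  centers <- seq(10.5, 22.5, length.out = n_clusters)
  compartments <- rep_len(c("synapse", "mitochondrion", "nucleosome",
                            "membrane", "extracellular_matrix"), n_clusters)
  insoluble <- runif(n_proteins) < prop_insoluble
  ubiquitinated <- insoluble & runif(n_proteins) < 0.5
  n_pep <- sample(3:8, n_proteins, replace = TRUE)
  peptides <- purrr::map(n_pep, function(np) {
    tibble::tibble(peptide = .random_peptides(np),
                   charge = sample(2:3, np, replace = TRUE))
  })
  tibble::tibble(
    protein = ids, k0 = k0, lambda = runif(n_proteins, 0, 0.15),
    archetype = archetype, center = centers[archetype],
    amp = archetype_amp, width = archetype_width,
    compartment = compartments[archetype],
    insoluble = insoluble, ubiquitinated = ubiquitinated,
    complex = complex, peptides = peptides
  )
}

# age-modulated degradation rate: Gaussian dip of depth amp at the archetype
# center (slower degradation -> FA bump at that age)
.k_at_age <- function(k0, age, center, amp, width) {
  k0 * (1 - amp * exp(-(age - center)^2 / (2 * width^2)))
}

#' Simulate ground-truth fractional abundance for a cohort
#'
#' First-order turnover with a long-lived fraction:
#' `FA_true = lambda + (1 - lambda) * exp(-k(a_eff) * T)` with `T` the window
#' duration (3 months), `a_eff` the window midpoint minus the sex shift for
#' females, and `k()` the archetype-modulated rate. Replicate-level FA adds
#' logit-normal jitter (`sigma`) around the group truth.
#'
#' @param design A [cohort_design()].
#' @param panel A [protein_panel()] tibble.
#' @param sigma Logit-scale replicate noise SD.
#' @return A `cohort_truth`: list with `design`, `panel`, `samples`, `truth`
#'   (protein x sex x window group truth) and `sample_truth` (protein x
#'   sample, columns `fa_group` and `fa_sample`).
#' @export
#' @examples
#' tr <- simulate_truth(cohort_design(seed = 7),
#'                      protein_panel(300, seed = 7))
#' head(tr$truth)
simulate_truth <- function(design, panel, sigma = 0.15) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  samples <- cohort_samples(design)
  shift <- setNames(ifelse(design$sexes == "female", design$sex_shift, 0),
                    design$sexes)
  truth <- tidyr::expand_grid(
    protein = panel$protein,
    tidyr::expand_grid(sex = design$sexes, design$windows)
  ) |>
    dplyr::left_join(
      dplyr::select(panel, "protein", "k0", "lambda", "center", "amp",
                    "width", "archetype"),
      by = "protein"
    ) |>
    dplyr::mutate(
      a_eff = .data$mid - unname(shift[.data$sex]),
      k = .k_at_age(.data$k0, .data$a_eff, .data$center, .data$amp,
                    .data$width),
      fa_true = .data$lambda + (1 - .data$lambda) *
        exp(-.data$k * .data$duration)
    ) |>
    dplyr::select("protein", "sex", "window", "age", "k", "fa_true",
                  "archetype")
  sample_truth <- samples |>
    dplyr::inner_join(truth, by = c("sex", "window", "age"),
                      relationship = "many-to-many") |>
    dplyr::mutate(
      fa_group = .data$fa_true,
      fa_sample = plogis(qlogis(pmin(pmax(.data$fa_true, 1e-8), 1 - 1e-8)) +
                           rnorm(dplyr::n(), 0, sigma))
    ) |>
    dplyr::select("protein", "sample", "sex", "age", "window", "replicate",
                  "fa_group", "fa_sample")
  structure(list(design = design, panel = panel, samples = samples,
                 truth = truth, sample_truth = sample_truth),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d proteins x %d samples (%d windows, %s)\n",
              nrow(x$panel), nrow(x$samples), nrow(x$design$windows),
              paste(x$design$sexes, collapse = "/")))
  invisible(x)
}

# -- MS1 simulation -----------------------------------------------------------

# chromatographic/envelope layout shared by all samples of a cohort: peptide
# retention-time centers are reassigned until no two peptides have envelope
# lines within 15 ppm while co-eluting (so XICs are interference-free), and
# the old/new envelope line tables are computed once.
.ms1_layout <- function(truth, label = "n15", enrichment = 0.96,
                        trunc = 1e-4, rt_span = c(300, 15900),
                        envelope_cache = NULL) {
  panel <- truth$panel
  set.seed(truth$design$seed + 1L)
  peptides <- panel |>
    dplyr::select("protein", "peptides") |>
    tidyr::unnest("peptides") |>
    dplyr::mutate(pep_id = dplyr::row_number(), .before = 1)
  cache <- envelope_cache %||% new.env(parent = emptyenv())
  acc <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    pair <- .envelope_pair(cache, peptides$peptide[i], peptides$charge[i],
                           label, enrichment, trunc, NULL)
    n_o <- nrow(pair$old); n_n <- nrow(pair$new)
    acc[[i]] <- list(
      pep_id = rep.int(i, n_o + n_n),
      pool = rep(c("old", "new"), c(n_o, n_n)),
      mz = c(pair$old$mz, pair$new$mz),
      abundance = c(pair$old$abundance, pair$new$abundance)
    )
  }
  lines <- tibble::tibble(
    pep_id = unlist(lapply(acc, `[[`, "pep_id"), use.names = FALSE),
    pool = unlist(lapply(acc, `[[`, "pool"), use.names = FALSE),
    mz = unlist(lapply(acc, `[[`, "mz"), use.names = FALSE),
    abundance = unlist(lapply(acc, `[[`, "abundance"), use.names = FALSE)
  )

  n_pep <- nrow(peptides)
  # peptide pairs with any envelope lines within 15 ppm must never co-elute;
  # build the conflict graph once from the mz-sorted line list
  ln <- lines[order(lines$mz), ]
  pair_a <- integer(0); pair_b <- integer(0)
  d <- 1L
  repeat {
    n <- nrow(ln)
    if (d >= n) break
    i1 <- seq_len(n - d); i2 <- i1 + d
    near_mz <- (ln$mz[i2] - ln$mz[i1]) / ln$mz[i1] * 1e6 <= 15
    if (!any(near_mz)) break
    cross <- near_mz & ln$pep_id[i1] != ln$pep_id[i2]
    pair_a <- c(pair_a, pmin(ln$pep_id[i1][cross], ln$pep_id[i2][cross]))
    pair_b <- c(pair_b, pmax(ln$pep_id[i1][cross], ln$pep_id[i2][cross]))
    d <- d + 1L
  }
  conflicts <- unique(cbind(pair_a, pair_b))
  nbrs <- vector("list", n_pep)
  for (r in seq_len(nrow(conflicts))) {
    a <- conflicts[r, 1]; b <- conflicts[r, 2]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  # greedy schedule: place each peptide at the first candidate retention time
  # at least 60 s from every already-placed conflict partner
  rt <- runif(n_pep, rt_span[1], rt_span[2])
  placed <- logical(n_pep)
  for (i in seq_len(n_pep)) {
    partners <- nbrs[[i]]
    partners <- partners[placed[partners]]
    if (length(partners) > 0) {
      cand <- c(rt[i], runif(40, rt_span[1], rt_span[2]))
      ok <- vapply(cand, function(t0) {
        all(abs(t0 - rt[partners]) >= 60)
      }, logical(1))
      if (!any(ok)) {
        rlang::abort("Could not place a peptide without XIC interference.")
      }
      rt[i] <- cand[which(ok)[1]]
    }
    placed[i] <- TRUE
  }
  peptides$rt_center <- rt
  peptides$base_area <- rlnorm(n_pep, log(1e6), 0.5)
  list(peptides = peptides, lines = lines, trunc = trunc, label = label,
       enrichment = enrichment, cache = cache)
}

#' Simulate the MS1 spectra and PSM table for one sample
#'
#' Emits Gaussian elution peaks (sigma 6 s, 3-s scan spacing, +-3.5 sigma)
#' for every old/new envelope line of every peptide; the old/new area ratio
#' equals the sample's true FA and each peak carries multiplicative
#' mean-one lognormal noise of coefficient of variation `noise_cv`. Peak
#' intensities are normalized so the trapezoidal integral of each line equals
#' its target area exactly, making the noiseless round trip exact.
#'
#' @param truth A `cohort_truth`.
#' @param sample_id One sample id from `truth$samples`.
#' @param layout Internal chromatographic layout; pass the result of a
#'   previous call (`attr(value, "layout")`) to amortize envelope work across
#'   samples, or leave `NULL`.
#' @param noise_cv Peak-level multiplicative noise CV (0 = noiseless).
#' @param seed Integer seed for this sample's noise.
#' @return List with `spectra` (scan, rt, mz, intensity), `psms` (peptide,
#'   protein, charge, rt, sequence, qvalue) and the reusable `layout`.
#' @export
simulate_ms1_sample <- function(truth, sample_id, layout = NULL,
                                noise_cv = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (is.null(layout)) layout <- .ms1_layout(truth)
  set.seed(seed)
  st <- truth$sample_truth[truth$sample_truth$sample == sample_id, ]
  if (nrow(st) == 0) rlang::abort(sprintf("Unknown sample '%s'.", sample_id))
  pep <- layout$peptides |>
    dplyr::inner_join(dplyr::select(st, "protein", "fa_sample"),
                      by = "protein") |>
    dplyr::mutate(area = .data$base_area * rlnorm(dplyr::n(), 0, 0.2))

  # per line: pool area = envelope abundance x pool share of the peptide area
  ln <- layout$lines |>
    dplyr::inner_join(
      dplyr::select(pep, "pep_id", "rt_center", "area", "fa_sample"),
      by = "pep_id") |>
    dplyr::mutate(line_area = .data$abundance * .data$area *
                    ifelse(.data$pool == "old", .data$fa_sample,
                           1 - .data$fa_sample))

  dt <- 3; sigma <- 6; half <- 21
  offsets <- seq(-half, half, by = dt)
  n_off <- length(offsets)
  center_snap <- round(ln$rt_center / dt) * dt
  rt_s <- rep(center_snap, each = n_off) + rep(offsets, nrow(ln))
  rt_c <- rep(ln$rt_center, each = n_off)
  w <- exp(-(rt_s - rt_c)^2 / (2 * sigma^2))
  # normalize so the trapezoid over the emitted scans integrates to 1
  wm <- matrix(w, nrow = n_off)
  tw <- dt * (colSums(wm) - (wm[1, ] + wm[n_off, ]) / 2)
  w <- w / rep(tw, each = n_off)
  intensity <- rep(ln$line_area, each = n_off) * w
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    intensity <- intensity *
      rlnorm(length(intensity), -sdlog^2 / 2, sdlog)
  }
  spectra <- tibble::tibble(
    scan = as.integer(rt_s / dt),
    rt = rt_s,
    mz = rep(ln$mz, each = n_off),
    intensity = intensity
  )
  psms <- layout$peptides |>
    dplyr::transmute(peptide = .data$peptide, protein = .data$protein,
                     charge = .data$charge, rt = .data$rt_center,
                     sequence = .data$peptide, qvalue = 0)
  list(spectra = spectra, psms = psms, layout = layout, sample = sample_id)
}

#' Simulate a full MS1 dataset
#'
#' @inheritParams simulate_ms1_sample
#' @param samples Sample ids (default all in the design).
#' @param seed Base seed; sample i uses `seed + i`.
#' @return Tibble with `sample` and list-columns `spectra`, `psms`.
#' @export
simulate_ms1_dataset <- function(truth, samples = NULL, noise_cv = 0.1,
                                 seed = 1L) {
  samples <- samples %||% truth$samples$sample
  layout <- .ms1_layout(truth)
  sims <- purrr::imap(setNames(samples, samples), function(s, nm) {
    simulate_ms1_sample(truth, s, layout, noise_cv,
                        seed = seed + match(s, samples))
  })
  tibble::tibble(
    sample = samples,
    spectra = purrr::map(sims, "spectra"),
    psms = purrr::map(sims, "psms")
  )
}

#' MS1 round trip: simulate, quantify, roll up
#'
#' Streams one sample at a time through [simulate_ms1_sample()],
#' [quantify_ms1()] and [rollup_protein_fa()], sharing the envelope cache, and
#' returns protein-level FA joined with the per-sample ground truth.
#'
#' @inheritParams simulate_ms1_dataset
#' @param ppm_tol XIC tolerance in ppm.
#' @return Tibble: `protein`, `sample`, `n_peptides`, `fa`, `fa_sample`
#'   (truth), `fa_group`.
#' @export
ms1_pipeline_fa <- function(truth, samples = NULL, noise_cv = 0.1, seed = 1L,
                            ppm_tol = 10) {
  samples <- samples %||% truth$samples$sample
  layout <- .ms1_layout(truth)
  out <- purrr::map(seq_along(samples), function(i) {
    sim <- simulate_ms1_sample(truth, samples[i], layout, noise_cv,
                               seed = seed + i)
    pept <- quantify_ms1(sim$spectra, sim$psms,
                         label = layout$label,
                         enrichment = layout$enrichment,
                         ppm_tol = ppm_tol, trunc = layout$trunc,
                         envelope_cache = layout$cache)
    prot <- rollup_protein_fa(pept)
    prot$sample <- samples[i]
    prot
  }) |> dplyr::bind_rows()
  dplyr::left_join(
    out,
    dplyr::select(truth$sample_truth, "protein", "sample", "fa_sample",
                  "fa_group"),
    by = c("protein", "sample")
  )
}

# -- TMT simulation -----------------------------------------------------------

#' Assign cohort samples to TMT plexes
#'
#' Fills 10-plex layouts sex by sex: nine sample channels plus one bridge
#' channel (`c10`) per plex.
#'
#' @param samples Sample table from [cohort_samples()].
#' @param plex_size Channels per plex (default 10, one reserved for the
#'   bridge).
#' @return Layout tibble: `plex`, `channel`, `sample`, `is_bridge`.
#' @export
tmt_layout <- function(samples, plex_size = 10) {
  per_plex <- plex_size - 1
  chunks <- samples |>
    dplyr::arrange(.data$sex, .data$age, .data$replicate) |>
    dplyr::group_by(.data$sex) |>
    dplyr::mutate(plex_in_sex = (dplyr::row_number() - 1) %/% per_plex,
                  slot = (dplyr::row_number() - 1) %% per_plex + 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(plex = paste0(substr(.data$sex, 1, 1), .data$plex_in_sex + 1))
  sample_rows <- chunks |>
    dplyr::transmute(plex = .data$plex,
                     channel = sprintf("c%02d", .data$slot),
                     sample = .data$sample, is_bridge = FALSE)
  bridge_rows <- sample_rows |>
    dplyr::distinct(.data$plex) |>
    dplyr::mutate(channel = sprintf("c%02d", plex_size),
                  sample = "bridge", is_bridge = TRUE)
  dplyr::bind_rows(sample_rows, bridge_rows) |>
    dplyr::arrange(.data$plex, .data$channel)
}

#' Simulate split-pool TMT reporter matrices
#'
#' Per protein and channel, old and new pool intensities reproduce the
#' sample's true FA; each pool is split over several PSM rows with their own
#' multiplicative noise. Per-channel loading factors (lognormal, plus any
#' injected `distort` factors) and per-plex batch factors are applied to both
#' pools, exercising loading normalization and bridge alignment. The bridge
#' channel carries a common reference pool (cohort-average FA per protein).
#'
#' @param truth A `cohort_truth`.
#' @param layout Layout from [tmt_layout()] (default: built from the truth).
#' @param noise_cv PSM-level multiplicative noise CV.
#' @param psms_per_protein PSM rows per protein and pool.
#' @param loading_sd Lognormal SD of channel loading factors.
#' @param distort Optional tibble (`plex`, `channel`, `factor`) of extra
#'   loading distortions.
#' @param seed Integer seed.
#' @return List: `old`, `new` (long reporter tibbles), `layout`, `truth`.
#' @export
simulate_tmt_dataset <- function(truth, layout = NULL, noise_cv = 0.1,
                                 psms_per_protein = 3, loading_sd = 0.2,
                                 distort = NULL, seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  layout <- layout %||% tmt_layout(truth$samples)
  if (!any(layout$is_bridge)) rlang::abort("Layout has no bridge channel.")
  set.seed(seed)
  panel <- truth$panel
  a_base <- setNames(rlnorm(nrow(panel), log(1e5), 0.6), panel$protein)
  bridge_fa <- truth$sample_truth |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(fa = mean(.data$fa_sample), .groups = "drop")
  ch_fa <- layout |>
    dplyr::left_join(truth$sample_truth, by = "sample",
                     relationship = "many-to-many")
  # bridge channels get the reference pool
  br <- ch_fa[ch_fa$is_bridge, c("plex", "channel", "is_bridge")] |>
    dplyr::distinct() |>
    tidyr::expand_grid(bridge_fa) |>
    dplyr::rename(fa_sample = "fa") |>
    dplyr::mutate(sample = "bridge")
  ch_fa <- dplyr::bind_rows(
    ch_fa[!ch_fa$is_bridge,
          c("plex", "channel", "is_bridge", "sample", "protein", "fa_sample")],
    br[, c("plex", "channel", "is_bridge", "sample", "protein", "fa_sample")]
  )
  loading <- layout |>
    dplyr::distinct(.data$plex, .data$channel) |>
    dplyr::mutate(loading = rlnorm(dplyr::n(), 0, loading_sd))
  if (!is.null(distort)) {
    loading <- loading |>
      dplyr::left_join(distort, by = c("plex", "channel")) |>
      dplyr::mutate(loading = .data$loading *
                      dplyr::coalesce(.data$factor, 1)) |>
      dplyr::select(!"factor")
  }
  plex_factor <- tibble::tibble(plex = unique(layout$plex),
                                batch = rlnorm(length(unique(layout$plex)),
                                               0, 0.3))
  sdlog <- sqrt(log(1 + noise_cv^2))
  psm_w <- tibble::tibble(
    protein = rep(panel$protein, each = psms_per_protein),
    psm_slot = rep(seq_len(psms_per_protein), nrow(panel)),
    w = runif(nrow(panel) * psms_per_protein, 0.5, 1.5)
  ) |>
    dplyr::group_by(.data$protein) |>
    dplyr::mutate(w = .data$w / sum(.data$w)) |>
    dplyr::ungroup()

  base <- ch_fa |>
    dplyr::left_join(loading, by = c("plex", "channel")) |>
    dplyr::left_join(plex_factor, by = "plex") |>
    dplyr::mutate(a = unname(a_base[.data$protein]) * .data$loading * .data$batch)

  make_pool <- function(pool) {
    base |>
      dplyr::inner_join(psm_w, by = "protein",
                        relationship = "many-to-many") |>
      dplyr::mutate(
        psm_id = paste0(.data$protein, "_", .data$psm_slot),
        share = if (pool == "old") .data$fa_sample else 1 - .data$fa_sample,
        intensity = .data$a * .data$w * .data$share *
          (if (noise_cv > 0) rlnorm(dplyr::n(), -sdlog^2 / 2, sdlog) else 1)
      ) |>
      dplyr::select("psm_id", "protein", "plex", "channel", "intensity")
  }
  old <- make_pool("old")
  new <- make_pool("new")
  list(old = old, new = new, layout = layout, truth = truth)
}

# -- proteasome-inhibition pulse ----------------------------------------------

#' Simulate a 7-day heavy-lysine pulse with partial proteasome inhibition
#'
#' Two arms (vehicle and inhibitor, `n_per_arm` animals each) labeled with
#' 13C6-lysine for `duration` days. The inhibited arm degrades the
#' proteasome-associated set (21 subunits plus `n_substrates` co-purifying
#' substrates) at `k * factor`, so its light (12C6, old) FA is
#' `exp(-k * factor * t)` versus `exp(-k * t)` in the vehicle arm, and the
#' steady-state abundance of those proteins is inflated by `1 / factor`
#' (synthesis unchanged, degradation scaled).
#'
#' @param n_per_arm Animals per arm.
#' @param factor Residual degradation fraction in the treated arm (0, 1].
#' @param duration Pulse length in days.
#' @param k_mean Median degradation rate (per day) of the
#'   proteasome-associated set.
#' @param n_substrates Co-purifying substrate proteins.
#' @param n_background Unaffected background proteins.
#' @param sigma Logit-scale replicate FA noise SD.
#' @param abundance_cv Replicate abundance noise CV.
#' @param seed Integer seed.
#' @return List: `truth` (protein x arm `fa_true`, `abundance_fold`), `fa`
#'   (long per-sample measured FA), `abundance` (long), `arms` (sample ->
#'   arm), `subunits`, `substrates`.
#' @export
simulate_inhibition <- function(n_per_arm = 5, factor = 0.5, duration = 7,
                                k_mean = 0.1, n_substrates = 50,
                                n_background = 429, sigma = 0.15,
                                abundance_cv = 0.15, seed = 1L) {
  if (factor <= 0 || factor > 1) rlang::abort("`factor` must be in (0, 1].")
  set.seed(seed)
  subunits <- c(paste0("Psma", 1:7), paste0("Psmb", 1:7),
                paste0("Psmc", 1:6), "Psmd1")
  substrates <- sprintf("Sub%03d", seq_len(n_substrates))
  background <- sprintf("Bkg%03d", seq_len(n_background))
  proteins <- c(subunits, substrates, background)
  assoc <- proteins %in% c(subunits, substrates)
  k <- ifelse(assoc, k_mean * rlnorm(length(proteins), 0, 0.25),
              0.15 * rlnorm(length(proteins), 0, 0.4))
  truth <- tidyr::expand_grid(protein = proteins,
                              arm = c("vehicle", "marizomib")) |>
    dplyr::mutate(
      k = rep(k, each = 2),
      assoc = rep(assoc, each = 2),
      k_eff = ifelse(.data$arm == "marizomib" & .data$assoc,
                     .data$k * factor, .data$k),
      fa_true = exp(-.data$k_eff * duration),
      abundance_fold = ifelse(.data$arm == "marizomib" & .data$assoc,
                              1 / factor, 1)
    )
  arms <- tibble::tibble(
    sample = c(sprintf("veh_r%d", seq_len(n_per_arm)),
               sprintf("mzb_r%d", seq_len(n_per_arm))),
    arm = rep(c("vehicle", "marizomib"), each = n_per_arm)
  )
  per_sample <- truth |>
    dplyr::inner_join(arms, by = "arm", relationship = "many-to-many")
  a_base <- setNames(rlnorm(length(proteins), log(1e5), 0.6), proteins)
  sdlog <- sqrt(log(1 + abundance_cv^2))
  per_sample <- per_sample |>
    dplyr::mutate(
      fa = plogis(qlogis(pmin(pmax(.data$fa_true, 1e-8), 1 - 1e-8)) +
                    rnorm(dplyr::n(), 0, sigma)),
      abundance = unname(a_base[.data$protein]) * .data$abundance_fold *
        rlnorm(dplyr::n(), -sdlog^2 / 2, sdlog)
    )
  list(
    truth = dplyr::select(truth, "protein", "arm", "k_eff", "fa_true",
                          "abundance_fold"),
    fa = dplyr::select(per_sample, "protein", "sample", "fa"),
    abundance = dplyr::select(per_sample, "protein", "sample", "abundance"),
    arms = arms, subunits = subunits, substrates = substrates,
    factor = factor, duration = duration
  )
}

#' Annotation fixture aligned with the planted compartments
#'
#' Builds a GMT-compatible term map: one term per planted compartment whose
#' members are exactly the proteins annotated to it, plus decoy terms drawn
#' uniformly from the panel at background rate.
#'
#' @param panel A [protein_panel()] tibble.
#' @param n_decoys Number of decoy terms.
#' @param decoy_size Members per decoy term.
#' @param seed Integer seed.
#' @return Named list of protein sets.
#' @export
annotation_fixture <- function(panel, n_decoys = 20, decoy_size = 30,
                               seed = 1L) {
  set.seed(seed)
  real <- split(panel$protein, panel$compartment)
  decoys <- setNames(
    purrr::map(seq_len(n_decoys),
               function(i) sample(panel$protein, decoy_size)),
    sprintf("decoy%02d", seq_len(n_decoys))
  )
  c(real, decoys)
}
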