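---
title: "Models and methods behind turnoverFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind turnoverFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnoverFA)
library(dplyr)
```

`turnoverFA` quantifies relative protein turnover from pulse-step
stable-isotope metabolic labeling. This vignette describes the models, the
numerical choices and the design decisions the package makes, and what the
synthetic cohort does and does not establish about real data.

## Fractional abundance as the turnover metric

During a labeling window only newly synthesized proteins incorporate the
heavy isotope (¹⁵N from enriched chow, or ¹³C₆-lysine during a short pulse).
The old (pre-existing) and new pools of a peptide are distinguishable in the
mass domain, and the **fractional abundance** of the old pool,
$\mathrm{FA} = I_{old}/(I_{old}+I_{new})$, is a unitless measure of
persistence: FA near 1 marks a long-lived pool, FA near 0 a rapidly renewed
one. FA is a *relative* quantity — it says nothing about absolute synthesis
or degradation fluxes, which is why the package pairs it with NSAF
spectral-count abundance when abundance changes matter.

## Isotopologue envelopes

The MS1 route needs the theoretical isotopologue envelope of each peptide
species. A peptide's elemental composition is the sum of its residue
formulas plus terminal water plus modification contributions
(`peptide_composition()`). Envelopes are computed by convolving per-element
isotope distributions — binomial/multinomial in the atom counts — and
binning by neutron-count shift from the monoisotopic species
(`isotope_envelope()`). Each bin keeps its exact probability-weighted mass,
so monoisotopic and mean masses are exact, and the whole computation runs in
milliseconds per peptide via binary powering of the single-atom
distribution.

Numerical choices:

* A single embedded isotope table (`isotope_table()`, IUPAC-style masses and
  abundances) is shared by the implementation, the tests' brute-force
  enumeration oracle and the acceptance script, so the two routes can be
  compared at $10^{-10}$ tolerance without constant mismatches.
* Truncation threshold: bins below `trunc` (default $10^{-6}$) relative
  abundance are dropped and the envelope renormalized. The MS1 round trip
  uses $10^{-4}$ on both the emission and fitting side; what matters for
  unbiased deconvolution is that both sides share the threshold.
* The ¹⁵N scheme sets the per-atom probability of ¹⁵N to $p$ and leaves all
  other elements natural. The chow enrichment level is not a measured
  quantity here; the generator default $p = 0.96$ is a conventional
  high-enrichment value, stated as a parameter, and the deconvolution is
  insensitive to its exact value as long as the same $p$ is used for the
  theoretical envelopes.
* ¹³C₆-lysine is modeled exactly: six carbons per labeled lysine leave the
  natural-carbon pool and contribute a fixed $+6.020129$ Da.
* Modifications are pure mass deltas, except carbamidomethyl and TMT whose
  C/H/N/O compositions enter the envelope (TMT's four ¹³C and one ¹⁵N are a
  fixed mass offset outside the natural pools). This matters because a TMT
  tag adds eight natural carbons to the convolution.
* Proton mass 1.007276 Da for m/z conversion; charge 0 returns neutral
  masses.

## MS1 deconvolution

For each PSM the package reconstructs the XIC area of every theoretical
envelope line (trapezoidal integration over the retention-time window;
matching tolerance 10 ppm — a chromatogram-extraction tolerance, narrower
than a search engine's precursor tolerance) and solves

$$\min_{a_{old},\,a_{new} \ge 0} \lVert y - a_{old}x_{old} - a_{new}x_{new}\rVert^2$$

by exact two-column non-negative least squares: the unconstrained $2\times2$
solution when feasible, otherwise the better single-column fit. With the
envelope shapes normalized to unit area, the coefficients *are* the
integrated old/new areas, and $w = a_{old}/(a_{old}+a_{new})$ is the peptide
FA. Grid lines closer than the matching tolerance are merged (they are
unresolvable by construction), each observed peak contributes to its nearest
target only, and envelope pairs with cosine similarity above 0.99 after
binning are flagged `unresolvable` and excluded from the rollup — NNLS is
ill-conditioned there and no weighting scheme rescues it. Charge states are
fitted independently and their areas summed per peptide; the peptide→protein
rollup is likewise area-weighted (`rollup_protein_fa()`), which keeps the
protein FA inside the range of its peptide FAs and matches
chromatogram-area quantification (a mean-of-peptide-FA mode is available).

No intensity floor is applied anywhere; identification-level filtering is
minimum peptide length 5 and q ≤ 0.01, with an optional diGly
(+114.042927) subset for the ubiquitinated pool. Database searching itself
is out of scope — the package consumes PSM tables with label-pool
assignments.

## Split-pool TMT

With PSM pools separated before reporter quantification, per-protein
per-channel FA is $\sum I_{old}/(\sum I_{old}+\sum I_{new})$
(`channel_fa()`). Two normalization questions were genuinely open:

* *What does "dividing over the sum of all channels" normalize?* The package
  reads it as per-channel total equalization (loading correction), which
  `normalize_total()` implements per plex. But normalizing the old and new
  pool matrices **separately** provably biases FA whenever the mean FA
  differs across channels — which is exactly the age signal the design
  plants in the channels. The pipeline default (`tmt_fa(normalize =
  "joint")`) therefore derives one loading factor per physical channel from
  the combined old+new totals and applies it to both pools: the physical
  loading of a channel is the total material in it, a shared factor cancels
  in the FA ratio, and combined channel sums still equalize. The per-pool
  literal reading remains available as `normalize = "per_pool"`.
* *Bridge alignment level.* Factors are computed on protein-level aggregated
  bridge intensities with a median-of-ratios estimator (reference = first
  plex), which is robust when few proteins are shared and is idempotent.

Missing channels propagate as missing; no isotopic-impurity correction is
attempted (out of scope).

## Group statistics

`compare_groups()` exposes the tests the field's figure legends alternate
between: one-way ANOVA with Tukey HSD, Kruskal–Wallis, two-way ANOVA, Welch
and Student t. "Kruskal–Wallis with Tukey's multiple comparisons" is a
nonstandard pairing, so the Kruskal–Wallis post-hoc defaults to Dunn's
rank-sum z tests with BH adjustment (the statistically standard choice,
implemented directly since no installed package provides it) and offers
Tukey-on-ranks as a fidelity mode. `median_adjust()` uses subtraction rather
than division so that subsequent row z-scoring is unaffected by the choice.
`diff_abundance()` runs per-protein Welch t on log2 abundances with BH
across proteins at $\alpha = 0.05$ — the source analyses do not state their
criterion, so the package uses the conventional one and records it in the
output.

## Trend clustering

FA profiles (protein × age, replicate-averaged) are row z-scored with the
$n-1$ standard deviation (the convention of common heatmap tooling; stated
so tests can be exact), zero-variance rows dropped with a message. k-means
(Euclidean, 50 random starts, 300 iterations, seed required) is run over
`k_range` 2–8; the mean silhouette (via `cluster::silhouette`) selects k
among solutions whose every cluster has at least `min_size = 10` proteins —
the size rule filters candidate k values rather than merging small clusters.
Ties go to the smaller k. Requiring an explicit seed makes cluster outputs
byte-reproducible.

## Enrichment and overlap

Overrepresentation uses the one-sided Fisher test (hypergeometric upper
tail) against a user-supplied background — the aggregated identified
proteins, not the genome — with BH-FDR at 0.05. Term ranking uses
$(-\log_{10}\mathrm{FDR}) \times \log_2(\mathrm{fold})$, the package's own
definition of a "combined FDR and fold enrichment" score (no formula exists
to copy), with top 4 as the default report size. Set-overlap tests are
two-sided Fisher on the 2×2 table with the cross-product odds ratio, since
association rather than directional enrichment is the question there. No GO
graph propagation is performed; annotation input is plain GMT.

## The synthetic cohort

The generator exists so every stage is testable without the deposited animal
data. Its kinetic model is first-order decay with a long-lived fraction:

$$\mathrm{FA}_{true} = \lambda + (1-\lambda)\,e^{-k(a)\,T},$$

with $T = 3$ months, $k(a) = k_0\,(1 - A\,e^{-(a - c)^2/2w^2})$ a Gaussian
dip of the degradation rate centered on a cluster-specific age $c$ (slower
degradation → an FA bump there), and the female curve evaluated 9 months
earlier than the male one. This is the minimal generative model consistent
with old-pool FA data: the measurements are fractions, not rates, so a
richer synthesis/degradation model would be unidentifiable here. Defaults
(chosen once, as study conditions): 500 proteins, 5 archetypes with centers
at the window midpoints, dip depth $A = 0.6$ and width 2.5 months,
$k_0 \approx 0.25$/month lognormal, $\lambda \sim U(0, 0.15)$, replicate
jitter logit-normal $\sigma = 0.15$, 3–8 tryptic peptides per protein at
charge 2–3, five 3-month windows over ages 9–24 months, n = 4 per group
except n = 3 for the female 15 M and 24 M groups, 10% insoluble flags, and
the 34 proteasome subunit genes with complex-specific rates (19S slower
than 20S, so 19S FA is higher at every age).

Simulated MS1 data emit Gaussian elution peaks (σ = 6 s, 3-s scans) for
every envelope line, normalized so each line's trapezoidal integral equals
its target area exactly — the noiseless round trip is then exact to machine
precision, which is what isolates deconvolution errors from emission
artifacts. Peptide retention times are scheduled greedily on a 4.5-h
gradient so that no two peptides with envelope lines within 15 ppm co-elute
within 60 s; the simulation therefore contains **no** co-elution
interference, chromatographic drift, missed cleavages or co-isolation — the
round-trip accuracies (FA RMSE ≈ 0.004 at 10% peak noise) are upper bounds
on what matched real data would give, and passing tests demonstrate
correctness of the computation, not field performance. Peak-level noise is
mean-one lognormal at CV 10%.

The inhibition module models a 7-day heavy-lysine pulse with the
proteasome-associated set degraded at $k \cdot \mathrm{factor}$ in the
treated arm ($k \approx 0.1$/day, factor 0.5, n = 5 per arm) and
steady-state abundance inflated by $1/\mathrm{factor}$ (synthesis unchanged,
degradation scaled). The "21 subunits" quantified in such experiments are
not enumerated anywhere authoritative, so the generator uses the 14 20S
genes plus Psmc1–6 and Psmd1.

## Problem sizes and determinism

The test-suite and acceptance runs use the default 500-protein cohort for
the MS1 round trip (38 samples), TMT clustering and enrichment; oracle
comparisons run on 50-peptide panels and ≤ 60-element universes where
enumeration is exact. Every stochastic stage takes an explicit seed, and all
writers emit deterministic column order, so repeated runs are
byte-identical.

## Known limitations

* No peak picking from profile spectra, no retention-time alignment, no
  protein inference — PSM tables with pool assignments are the entry point.
* No isotopic-impurity correction for TMT reporters, no MS2/MS3 distinction.
* FA is relative; absolute rate constants are only available inside the
  generator's truth tables.
* Hierarchical clustering is not implemented: the analyses this package
  mirrors describe k-means with silhouette selection in their figures, and
  the one mention of hierarchical clustering conflicts with that; k-means is
  the implemented, tested path.
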