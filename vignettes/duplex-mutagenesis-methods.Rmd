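---
title: "Methods: duplex-sequencing mutagenesis analysis with duplexmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex-sequencing mutagenesis analysis with duplexmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmut)
```

## The problem

Duplex sequencing (DS) builds a consensus from both strands of each sequenced
DNA molecule, pushing the technical error rate to roughly one in ten million
bases. That is low enough to call rare somatic mutations directly from
genomic DNA, so a panel of genomic targets sequenced deeply in treated and
control animals yields, per animal: a list of somatic variant calls with the
number of duplex molecules carrying each variant, and the number of
duplex base pairs interrogated per target. `duplexmut` implements the
downstream analysis of such an experiment: clonality-aware mutation
frequencies, dose-response contrasts, genomic-feature stratification,
6-class and 96-channel trinucleotide spectra, signature matching,
multivariate sample classification, benchmark-dose estimation, and a
cross-assay comparison against a transgenic-reporter readout. A seeded
synthetic-cohort generator stands in for deposited raw data so every stage
is testable end to end.

The emulated study design is a 28-day oral benzo(a)pyrene (BaP) exposure in
MutaMouse males: dose groups 0 (vehicle), 12.5, 25 and 50 mg/kg/day with six
animals each, read out in bone marrow over a panel of twenty ~2.4 kb
autosomal targets (9 genic, 11 intergenic, 7 in inferred heterochromatin)
with ~850 million duplex bp per sample.

## Mutation frequency and clonality

A mutation frequency (MF) is unique mutations per duplex base pair. Identical
calls in more than one molecule of the same sample are treated as one clonal
expansion event: they count once for MF, and the multiplicity sum is kept for
a clone-inclusive MF (`mf_clonal`). The uniqueness key is
`(sample_id, chrom, pos, ref, alt)`; the same variant in two animals is two
independent mutations. Group MFs pool counts over pooled bp rather than
averaging per-animal ratios, which is exact under unequal depths; the
across-animal SD is attached for dose-level scopes.

Dose contrasts use a binomial GLM with logistic link on per-animal
aggregates (mutations out of duplex bp against dose as a factor), Wald z
statistics for each dose against control, and a step-down Holm-Sidak
adjustment, `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)` with a running maximum
(computed via `log1p`/`expm1` so p-values in the 1e-80 range survive
adjustment). The original analysis names a binomial GLMM; its random-effect
structure is unstated, so the package fits the fixed-effects GLM on
per-animal aggregates and exposes a quasi-binomial option that scales the
Wald SEs by the estimated dispersion. The approximation is flagged here
rather than hidden: with six animals per group and panel-pooled counts the
fixed-effect Wald contrasts are expected to be slightly anti-conservative
relative to a GLMM with animal-level random effects. Stratified analyses
(genic/intergenic, chromatin) fit and adjust within each stratum
independently. Dose groups with zero mutations get a 0.5-mutation/1-bp
continuity count, with a warning.

The GC association test discretizes targets at a GC threshold (default: the
panel mean; the emulated study used 42.9%) and reports the Type II Wald
chi-square for the GC-group term of a dose + GC-group binomial GLM, via
`car::Anova`.

## Spectra and channels

All spectra use the COSMIC convention: substitutions are reported on the
pyrimidine strand, giving six classes expanded by the 5'/3' flanking bases
into 96 channels ordered by class, then 5' base, then 3' base. Purine
reference calls are reverse-complemented at assignment time, so spectra are
invariant to strand flips of the input. Indels and MNVs are excluded from
the 96-channel spectra and tallied separately in the 6-class summary.
Normalizations: raw counts, proportions, per duplex bp, and per context bp
(each channel divided by the panel abundance of its trinucleotide times the
depth per site).

Between-group spectrum comparison follows the modified contingency-table
idea for mutant-count data: an overall Monte Carlo chi-square on the
groups x classes table with fixed row totals (`stats::chisq.test` with
`simulate.p.value = TRUE`), then per-class 2x2 follow-ups (class vs rest,
group vs control) adjusted across classes by Holm-Sidak. The Monte Carlo
variant is robust to the sparse cells that rare classes produce. CpG-site
mutation proportions count a CG dinucleotide once (not per strand): a site
is mutated if any deduplicated call hits either strand's C.

## Signature matching

Observed spectra are compared to a signature catalog by cosine similarity,
`a.b / (|a||b|)`, after converting the query to proportions (cosine itself
is scale-free). Catalogs are read from a 96-row TSV in catalog layout, are
reordered into canonical channel order, and must row-sum to 1 within 1e-3
(smaller drift is renormalized). The bundled five-signature catalog is
synthetic and built in code — a flat signature, a bulky-adduct C>A
signature, a CpG-deamination C>T signature, and T>C- and C>G-rich
signatures — so tests never download an external catalog. Published
similarity values against the real COSMIC catalog depend on the deposited
data and the catalog version and are deliberately out of scope.

## Ordination and classification

**Binomial distance.** For two count vectors the dissimilarity is
`sum_i [x_i ln(x_i/m_i) + y_i ln(y_i/m_i)] / n_i` over channels with
`n_i = x_i + y_i > 0`, `m_i = n_i/2`, and `0 ln 0 = 0`. The formula is
implemented directly (and is cross-checked against an independent
community-ecology implementation in the test suite).

**NMDS.** Non-metric multidimensional scaling minimizes Kruskal-style
stress by alternating pool-adjacent-violators (isotonic) regression of the
configuration distances on the observed dissimilarity ranks with
Guttman-transform coordinate updates; disparities are rescaled to the
configuration-distance norm each iteration so the configuration cannot
collapse. The monotone transformation in the stress formula is exactly this
isotonic fit — the standard reading of NMDS stress, whose published form
normalizes by the squared distances; on the monotone-transformed scale the
two normalizations coincide, and both vanish when a configuration reproduces
the observed ordering perfectly. The first restart starts from classical
metric scaling (principal coordinates), the rest from seeded Gaussian
configurations (20 restarts, `tol = 1e-6`, k = 2 by default); the
lowest-stress solution is returned and an uphill step ends a restart at the
previous configuration, so the stress trace is non-increasing by
construction. Non-convergence is reported in a flag, not an error.

**Mantel test.** Pearson correlation of the upper triangles with a
one-sided (greater) permutation p, `p = (1 + #{r* >= r}) / (n_perm + 1)`,
matching the convention in which a positive matrix association is the
alternative of interest.

**Nearest shrunken centroids.** For channel i and class k the standardized
centroid difference is `d_ik = (centroid_ik - overall_i) / (m_k (s_i + s0))`
with `m_k = sqrt(1/n_k - 1/n)`, `s_i` the pooled within-class SD and `s0`
the median of the `s_i` (the usual stabilizer; the source analysis states
only that SDs were used for normalization). Soft thresholding shrinks
`d_ik` toward zero by delta; delta is chosen from a grid (default 30 values
spanning 0 to `max |d_ik|`) by cross-validated error with ties broken
toward the largest delta — the most parsimonious model, as in the emulated
analysis, which selected delta 3.653 under 6-fold cross-validation. At
delta 0 the classifier is exactly nearest centroids; above `max |d_ik|` all
channels are inactive and predictions fall back to the class priors (equal
by default). Channel inputs are percent proportions per sample, matching
the percent units of the published centroids.

**Gaussian discriminant.** For an observation x and per-channel class means
and pooled SDs, `A` and `B` are the squared standardized distances to the
exposed and control centroids and
`P(exposed) = exp(-A/2) / (exp(-A/2) + exp(-B/2))`, computed as
`plogis((B - A)/2)` for stability. No prior term enters, consistent with
the published closed form; `prob_exposed` and `prob_control` are exact
complements.

A practical note from the synthetic recovery experiments: because the
generator draws channels multinomially, per-channel noise scales with the
square root of the channel proportion, so the strongest exposure channel
(`C[C>A]C`) carries a much larger standardized difference than its
companions and cross-validation typically retains it alone. Real
per-animal spectra are biologically overdispersed (per-channel SDs grow
roughly in proportion to their means), which is why the emulated analysis
retained three channels of comparable standardized weight. The
classification consequences are minor — mid-dose samples are called
exposed essentially always, low-dose samples in the high-80s to low-90s
percent — but channel-selection behaviour on synthetic cohorts should not
be over-interpreted.

## Benchmark doses

Continuous dose-response summaries (per-dose arithmetic mean, SD, n) are
fitted under a lognormal response with common log-scale variance;
arithmetic moments convert to log-scale moments by
`sdlog^2 = log(1 + (sd/mean)^2)`, `meanlog = log(mean) - sdlog^2/2`. The
six families (mu is the response median, a the background):

| model | mu(d) | free shape parameters |
|---|---|---|
| exp3 | `a exp(b d^g)` | b, g |
| exp5 | `a (c - (c-1) exp(-b d^g))` | b, c > 1, g |
| hill3 | `a (1 + c d / (b + d))` | b, c |
| hill5 | `a (1 + c d^g / (b^g + d^g))` | b, c, g |
| inv_exp | `a (1 + c exp(-b d^(-g)))` | b, c, g |
| log_normal | `a (1 + c pnorm(g log(d/b)))` | b, c, g |

The shape power g is constrained to [1, 4] for the `d^g` families, where
g < 1 would give an infinite slope at dose 0; the inverse-exponential and
log-normal curves are flat at dose 0 for any positive power, so their g
ranges over [0.25, 4]. The background a is profiled in closed form, which
(i) removes one optimization dimension and (ii) makes every BMD exactly
invariant to rescaling the response. Optimization is deterministic:
linearization-based starts (each family's inverse link is linear in log
dose for a candidate amplitude) plus a fixed crude grid, Nelder-Mead, then
a BFGS polish; the 5-parameter Hill additionally starts from the fitted
3-parameter Hill with g at its lower bound, which guarantees the nesting
inequality on the maximized likelihoods. The BMD at a benchmark response
(BMR, default 50%) solves `mu(d) = (1 + bmr) mu(0)` by bracketing and
bisection; a fit that never reaches the target within 10x the top dose
(e.g. a constant response) is excluded with a warning. `model_average`
takes the plain equal-weight mean of the converged models' BMDs; an
optional AIC inclusion window (the common screening rule) is available but
off by default.

Two points deserve caution. First, with four dose groups the four-shape
families interpolate the group means exactly, so their BMDs reflect pure
between-dose interpolation shape; when the BMR falls far below the first
tested dose (as for a steep transgene response), threshold-shaped families
(inverse exponential, log-normal) legitimately report later benchmark
doses than the exponential and Hill families, and the equal-weight average
inherits that spread. Second, published model-averaged BMDs depend on the
reference implementation's exact family parameterizations; the forms above
are documented precisely so the package's numbers are reproducible on
their own terms.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions stated above. Design choices, with rationale:

* **Depth.** Per-target duplex depth is lognormal with mean
  `depth_mean / n_targets` and CV `depth_cv` (default 0.05 — coverage in
  the emulated study was described as relatively even across targets and
  samples).
* **Counts.** Unique mutations per (sample, target) are Poisson with rate
  `MF_target x depth`; at MFs near 1e-7 a binomial with tiny p is
  indistinguishable. `MF_target` applies a genic reduction (default 23%
  in background, 42% at positive doses — per-dose because a single scalar
  cannot reproduce both published contrasts) and a heterochromatin
  multiplier (default 1.3, from the published 1.18e-6 vs 9.04e-7 split),
  renormalized so the panel-wide expectation equals the configured dose
  mean and fold-change arithmetic holds on average.
* **Channels.** Each SNV's channel is drawn from
  `(1 - w) control + w exposure`, with `w(dose)` equal to the excess-MF
  fraction `(dose_mf - base_mf)/dose_mf` — the fraction of mutations
  attributable to exposure if background processes continue unchanged.
  The control spectrum spreads the background class shares (32/22/16%
  C>A/C>G/C>T, remainder uniform over T classes) uniformly over flanks;
  the exposure spectrum is solved from the mixture identity so the
  expected pooled high-dose spectrum reproduces the published 61/14/11%
  class shares and the 4.23/10.3/4.00% discriminant channels exactly,
  with a mild additional excess on the CpG contexts `A[C>A]G`/`G[C>A]G`.
* **Positions.** Drawn uniformly among in-target sites whose
  pyrimidine-normalized context matches the channel, without replacement
  within a context — a sample cannot carry two identical "unique"
  mutations, and heavy channels are not silently thinned by birthday
  collisions. A context absent from a target resamples the channel.
* **Clones.** With per-dose probability `clone_prob` (defaults rising
  0.02 to 0.10 with dose, qualitatively matching the published rising
  clonal fraction) a record gains `1 + Geometric(mean clone_size_mean)`
  extra molecules; geometric is the minimal one-parameter choice since no
  clone-size distribution is published.
* **Indels/MNVs.** Generated as single-bp-scale events at rate
  `indel_fraction` (default 7%) without context structure; they are minor
  classes in the emulated data.
* **Seeding.** One global seed; per-sample substreams derive from it
  deterministically, so cohorts are byte-identical across runs and
  platforms.

What the generator does **not** emulate: biological overdispersion of
per-animal spectra (see the classification note above), inter-animal MF
heterogeneity beyond Poisson + depth variation, realistic CpG-site
saturation (the synthetic CpG excess is stylized; the generated
CpG-mutated fraction rises with dose but not at the published magnitude),
target-specific mutability beyond the three annotated modifiers, and any
read-level error process (duplex consensus error sits well below the
target MFs by design). Passing recovery tests therefore demonstrates that
the estimators are correct and unbiased under the stated stochastic model,
not that they are robust to every pathology of real data.

## Problem sizes used in the checks

The packaged checks run the full study geometry where the claim depends on
it — twenty replicate cohorts at the default configuration (24 samples,
~850 Mbp per sample) for dose-response and classification recovery, and
one full cohort for spectrum recovery — and scaled-down cohorts
(identical rates, 5e6-3e8 bp per sample) for structural and property
tests, where depth only changes counting noise. Oracle comparisons
(brute-force MF recounts, the 192-triple channel table, loop-computed
binomial distances) run on small cohorts by construction.

## Known limitations

* The GLM approximation to the published GLMM (above).
* BMD point estimates only; bootstrap confidence intervals are out of
  scope.
* No de novo signature extraction (NMF) and no exposure attribution by
  non-negative least squares; only spectrum construction, comparison and
  cosine matching.
* Published values that require the deposited per-animal data (regression
  R^2 of assay comparisons, COSMIC cosine values, NMDS stress values,
  Mantel r) are not reproduced; the corresponding machinery is validated
  by property-based tests and synthetic recovery instead.
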