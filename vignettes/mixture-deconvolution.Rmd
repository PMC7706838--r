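---
title: "Benchmarking stage-resolving marker panels by in silico mixture deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking stage-resolving marker panels by in silico mixture deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Erythroid maturation proceeds through an ordered series of precursor stages
(progenitors, ProE/EBaso, LBaso, Poly, Ortho - here labelled P1 to P5). Bulk
proteome measurements of sorted populations give one intensity profile per
stage, but real samples are rarely pure: a bulk pool is a mixture of stages
in unknown proportions. A small panel of stage-specific marker proteins, if
it truly resolves the stages, should let us read those proportions back out
of a bulk measurement. This package quantifies *how well* a given panel does
that, entirely in silico, and estimates absolute per-cell protein copy
numbers with the histone proteomic ruler.

Everything runs on simulated data with known ground truth, so every claim
the benchmark makes is checkable against the generating model.

## The mixture model and its estimator

Write $I_{ik}$ for the intensity of protein $k$ in pure stage $i$, and let
$a_i \ge 0$, $\sum_{i=1}^{K} a_i = 1$ be the stage composition of a bulk
sample. The benchmark assumes intensities mix linearly:

$$ I^{k}_{\mathrm{mix}} = \sum_{i=1}^{K} a_i\, I_{ik}, $$

or in matrix form over a marker panel, $\mathbf{i}_{\mathrm{mix}} = I\,\hat{\mathbf a}$
with the *signature matrix* $I$ (markers x stages). Estimation proceeds in
two passes:

1. solve $\min_{\hat a \ge 0} \lVert I \hat a - \mathbf{i}_{\mathrm{mix}}\rVert_2$
   over all markers (Lawson-Hanson active-set non-negative least squares,
   authored in the package; the KKT conditions hold at convergence);
2. rank markers by scaled residual $|I_k \hat a - i_{\mathrm{mix},k}| / \lVert I_k \rVert_2$,
   keep the best-fitting 90%, and re-solve on the retained markers;
3. normalize the refit solution by its Manhattan (L1) norm so
   $\sum_i \hat a_i = 1$.

The signature averages the *linear* (never log) intensities of replicates
2 and 4 of each stage; mixtures are synthesized from replicates 1 and 3, so
signature and mixture information never share a replicate. A guard rejects
signature input whose values all sit below 64, which almost always means a
log-transformed matrix was passed by mistake.

Two readings of "keep the top 90th percentile of best-fitting markers" are
possible; the package keeps the best 90% (discarding the worst decile),
because keeping only the top 10% would routinely leave fewer markers than
stages. Both the retained fraction and the ranking statistic are arguments
(`retain_fraction`, and the scaled-residual ranking is fixed but its scale
normalization prevents abundant markers from monopolizing retention). The
retained count is `max(n_stages, ceiling(0.9 * m - 1e-9))`: the epsilon
keeps floating-point noise in `0.9 * 100` from rounding 90 up to 91, and a
refit is never attempted with fewer markers than stages.

## Scoring: an ordinal earth-mover error

Confusing neighbouring stages is a smaller mistake than confusing a
progenitor with an orthochromatic erythroblast. The score is therefore the
1-D Wasserstein-1 distance between the true and estimated compositions on
the ordered stage axis with unit spacing:

$$ W_1(a, \hat a) = \sum_{k=1}^{K-1} \bigl| \textstyle\sum_{j \le k} (a_j - \hat a_j) \bigr|. $$

Moving 0.2 of mass one stage costs 0.2; moving it across the whole series
costs 0.8. $W_1$ is zero iff the compositions are equal, symmetric, and
satisfies the triangle inequality - properties the test suite asserts on
random simplex pairs. Stage spacing is configurable for non-uniform
developmental distances.

Three baselines calibrate the scale: `uniform` ($\hat a_i = 1/K$), `center`
(all mass on the middle stage) and `random` (a fresh flat-Dirichlet draw per
mixture, so its expected error depends only on the ratio distribution). One
geometric fact worth knowing when reading results: for a truth concentrated
entirely on an extreme stage, *every* estimator whose mean stage position is
central scores exactly $W_1 = 2$ (with $K = 5$), so uniform, center, and the
random control tie there; the center control is strictly the worst control
for truths split across both extremes.

## The synthetic proteome

`synth_config()` / `generate_proteome()` define the study conditions:

* **Design.** 3,000 protein groups x 5 ordered stages x 4 replicates.
  A few thousand proteins is the scale at which the preprocessing,
  permutation test and benchmark behave as they do on real DIA matrices
  while keeping a full run in seconds; all sizes are arguments.
* **Temporal structure.** Each background protein follows one of six
  archetypes - monotone up, monotone down, early peak, late peak, transient
  mid, U-shaped - scaled by a per-protein amplitude (gamma, mean 1.5 log2
  units). Six shapes span the qualitative variety of stage-resolved
  profiles; the true functional forms in any real dataset are unknown, and
  these are explicit stand-ins.
* **Noise.** Replicates are log-normal around the true stage mean. Each
  protein draws its own CV log-normally around the median `noise_cv = 0.15`
  with `noise_cv_spread = 0.5`, putting roughly a quarter of proteins above
  a 20% CV - the long-tailed replicate-CV profile typical of DIA
  proteomes. The log-scale sigma is `sqrt(log(1 + cv^2))`, so a protein
  with CV $c$ has exactly that coefficient of variation.
* **Dropout.** Missingness is logistic in log10 intensity (midpoint 4.0,
  steepness 1.5): censoring concentrates at low abundance (MNAR), which is
  the premise of downshifted-normal imputation. About 20% of cells go
  missing at the defaults.
* **Histones.** Ten histone groups whose summed mass at the first stage
  equals the DNA mass of a diploid genome (6.5 pg), declining 15% per stage
  transition (`histone_decline = 0.85`) to emulate histone release during
  chromatin condensation.
* **Planted markers.** Sorting (6 proteins, broad: log2 separability 2,
  abundant), known (22, separability 2) and SLC (18, separability 3.5)
  panels, each marker elevated in a target stage that cycles through the
  series. Curated markers draw their CV from the below-median half of the
  CV distribution, since real curated panels are selected for consistent
  quantification. Separabilities are set so the benchmark reproduces the
  qualitative structure expected of such panels: curated surface-marker
  sets resolve the extremes but blur adjacent intermediate stages, the SLC
  and data-driven panels do better, and the combined union does best.

What the generator does *not* emulate: peptide/spectrum-level effects,
correlated protein modules beyond the six shapes, batch effects, or any
real protein identities. Passing tests therefore demonstrate correctness of
the computations and reasonable behaviour under plausible conditions - not
performance on any particular real dataset.

## Preprocessing and the differential test

* **Completeness.** A protein is kept if observed in at least
  `min_fraction_per_stage` (default 0.75, i.e. 3 of 4 replicates) of at
  least one stage's replicates. The stricter 100%-in-one-stage variant is
  applied before ruler copy numbers. The 3-of-4 default resolves the
  quadruplicate-design / "all triplicates" ambiguity in favour of the
  weaker, configurable rule.
* **Imputation.** Missing log2 cells of each sample column are drawn from
  `Normal(mean_col - 1.8 sd_col, (0.3 sd_col)^2)`. Imputation is
  per-column because the downshift is only meaningful relative to each
  sample's own intensity distribution. Observed cells are never modified;
  a column with fewer than two observed values is an error.
* **Test statistic.** Per protein, a one-way ANOVA F across stages with an
  S0 regularization: `F = MSB / (sqrt(MSW) + s0)^2` with `s0 = 0.1`, which
  damps proteins whose significance rests on near-zero within-stage
  variance. Zero-variance proteins get F = 0 and q = 1 by convention.
* **Permutation FDR.** Stage labels are permuted across samples (250
  rounds), permuted statistics are pooled over all proteins, and the FDR at
  threshold $t$ is the permutation-expected count of statistics $\ge t$
  over the observed count; q-values are the suffix-minimum of that curve
  (step-up monotonization), clamped to [0, 1]. The pooling gives q-value
  resolution far below 1/250 because the null sample has
  proteins x permutations entries.
* **Clustering.** Significant proteins' per-stage *medians* are z-scored
  per protein and clustered hierarchically with Euclidean distance, cut at
  k = 6. The package defaults to Ward linkage (`ward.D2`): with noisy
  profiles, average linkage reliably splits off one or two outlier proteins
  as singleton clusters, leaving fewer than six usable temporal profiles
  and a crippled cluster-Top3 panel, whereas Ward yields balanced clusters
  that recover the six generating archetypes almost exactly. Average
  linkage remains one argument away.

## Panels

`cluster_top3` takes the three smallest-q proteins per cluster (ties broken
by larger F, then lexicographic id - panels are fully deterministic); six
clusters give the 18-protein panel. Curated panels are q-filtered at 0.01;
`combined` is their deduplicated union; `any20` draws 20 proteins from the
unfiltered list excluding every other panel, under its own child seed. A
panel whose usable signature has rank below the number of stages is skipped
with a warning rather than estimated - with four usable markers and five
stages the linear system cannot identify the composition. This does remove
the sorting panel from some runs: a rare dropout of an abundant marker gets
imputed far below its observed values, inflates its within-stage variance,
and costs it the q < 0.01 filter - precisely the failure mode completeness
filtering exists to limit.

## The proteomic ruler

Per sample, copies of protein $p$ are

$$ c_p = \frac{I_p \cdot m_{\mathrm{DNA}} \cdot N_A}{\left(\sum_{h \in \mathrm{histones}} I_h\right) \cdot M_p}, $$

with $m_{\mathrm{DNA}}$ = ploidy (2) x haploid DNA mass (3.25 pg,
~3.1 Gbp; an explicit, overridable setting) and $M_p$ the average molecular
mass. Total protein mass per cell is $\sum_p c_p M_p / N_A$ and cell volume
is mass over the assumed 200 g/l protein concentration - so volume x
concentration equals mass by construction, and any per-sample intensity
rescaling cancels. The core assumption is intensity proportional to protein
mass. Each sample column is converted separately (per-column averaging),
with a pooled per-stage mode available. Both median and summed copies are
reported per protein set, since either can be the quantity of interest.

One structural caveat the package documents rather than hides: because each
sample is renormalized to the fixed histone:DNA anchor, a genuine decline in
cellular histone content is invisible in ruler output - estimated histone
totals stay flat while every other protein's copies inflate
correspondingly in later stages. The round-trip test therefore plants
`histone_decline = 1` (the regime where the ruler's premise holds and
recovery is exact to floating point), and the declining-histone default run
reads the decline from the generator's ground truth.

## Determinism and the seed scheme

One master seed drives everything. Each stochastic stage (simulate, impute,
anova, panels, ratios, random control) derives a fixed child seed as
master + a stage-specific constant, so adding or reordering stages never
perturbs another stage's draws, and re-running any configuration reproduces
every artifact bit for bit. The 500 mixture compositions are drawn once and
shared by all panels, making panel comparisons paired.

## Numerical choices

* Flat Dirichlet (gamma(1) normalization) for random compositions: the
  only stated requirement is exchangeability over stages; rows sum to 1 to
  ~1e-16.
* NNLS convergence: active-set with iteration budget 50(K+1) and a
  pseudoinverse fallback for rank-deficient passive sets; on budget
  exhaustion the current feasible point is returned with a warning.
* Markers missing from a mixture's sources are dropped from that mixture's
  linear system, never zero-filled - a zero would be a fake observation
  with maximal leverage on the residual ranking.
* Off-simplex inputs to the error metric are rejected beyond 1e-6;
  estimates are L1-normalized to ~1e-9 before scoring.
* Mixture replicates are averaged (the per-replicate mode is an argument);
  degenerate cases (all-zero mixture, zero estimated total) are errors, not
  silent zeros.

## Problem sizes

The default study (3,000 proteins, 250 permutations, 500 mixtures, 6 panels
+ 3 controls) runs in a few seconds; the test suite, including two full
default runs and the brute-force simplex grids, takes well under a minute.
The grid-search oracle is exponential in stages and is deliberately limited
to three.

## Limitations

* All distributional choices in the generator are stand-ins; no real
  spectra, identities, or deposited data are used anywhere.
* Error magnitudes depend on the generator's noise and separability
  settings; only orderings and recovery properties are meaningful, and no
  number here is comparable to any published real-data error value.
* The benchmark validates resolution of *known* stage profiles; it says
  nothing about reference-free deconvolution or about samples containing
  cell states absent from the signature.
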