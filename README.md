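# erydecon

Reference-based deconvolution asks: given pure-stage proteome profiles of an
ordered developmental series, how accurately can a small panel of marker
proteins read the stage composition of a bulk sample back out of its
intensities? `erydecon` answers this for erythroid maturation
(progenitors → ProE/EBaso → LBaso → Poly → Ortho) with a fully simulated,
ground-truth-bearing pipeline, and adds absolute per-cell copy-number
estimation via the histone proteomic ruler. It is aimed at proteomics
bioinformaticians designing stage- or cell-type-resolving marker panels and
wanting an honest, reproducible benchmark of panel quality.

## The model

Intensities mix linearly: a bulk sample with stage fractions
$a_i \ge 0,\ \sum_i a_i = 1$ has mixture intensity
$I^k_{\mathrm{mix}} = \sum_i a_i I_{ik}$ for each marker $k$, i.e.
$\mathbf{i}_{\mathrm{mix}} = I \hat{\mathbf a}$ with signature matrix $I$
(markers × stages, averaged linear intensities of the signature
replicates). Fractions are estimated by non-negative least squares, the
worst-fitting 10% of markers are discarded, the system is re-solved, and
the result is L1-normalized onto the simplex. Panel quality is the
Wasserstein-1 distance between estimated and true compositions on the
ordered stage axis,
$W_1(a,\hat a) = \sum_{k<K} |\sum_{j\le k}(a_j - \hat a_j)|$, which prices
a confusion of distant stages higher than one of neighbours. Copy numbers
follow the proteomic ruler,
$c_p = I_p\, m_{\mathrm{DNA}} N_A / (\sum_h I_h \cdot M_p)$, anchoring the
summed histone intensity of each sample to the DNA mass of a diploid
genome.

The pipeline around this: simulate a 5-stage × 4-replicate DIA-style matrix
(six temporal archetypes, long-tailed replicate CV, MNAR dropout, declining
histones, planted marker panels) → completeness filter → downshifted-normal
imputation → S0-regularized ANOVA with permutation FDR → Ward clustering of
z-scored profiles → panel assembly (sorting / known / cluster-Top3 / SLC /
combined / any20) → 500-mixture benchmark with random, uniform and center
controls → ruler copy numbers.

## Worked example

```r
library(erydecon)
res <- run_pipeline(pipeline_config(seed = 1))
print(res$report)
```

```
evaluation_report: 8 panels/controls x 500 mixtures
           panel   n      min      q1  median    mean      q3     max
        combined 500 0.001582 0.02379 0.03693 0.03876 0.05286 0.09669
    cluster_top3 500 0.002426 0.02384 0.03910 0.04043 0.05456 0.10290
             slc 500 0.006212 0.06560 0.09777 0.11535 0.15726 0.48270
           known 500 0.042054 0.14852 0.19981 0.19649 0.24065 0.35440
 control_uniform 500 0.111586 0.40891 0.55253 0.60856 0.75220 1.74804
           any20 500 0.056983 0.28311 0.51315 0.61788 0.87303 2.14459
  control_random 500 0.110028 0.52229 0.75082 0.82360 1.04329 2.67953
  control_center 500 0.237661 1.01381 1.21639 1.20239 1.43538 1.90956
```

Each row summarizes the ordinal mixture-error distribution of one panel (or
baseline) over the same 500 random compositions: the combined panel
estimates stage fractions with a mean error of ~0.04 stage-units of
misplaced mass, every informative panel beats the 20-random-protein `any20`
control (which lands at the level of the data-blind uniform baseline), and
`center` (everything called P3) is worst. In this run the 6-marker sorting
panel lost too many members to the q-filter and signature completeness
rules to identify five stages, so it was skipped with a warning. Exact
values depend on the seeded simulation; re-running the same config
reproduces them bit for bit.

The staged walk-through lives in `analysis/01_simulate.R` …
`analysis/06_copy_numbers.R`; each script narrates one pipeline stage and
writes its tables under `results/pipeline/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
# ... through 06
```

## Package layout

* `R/` — simulator, preprocessing/ANOVA/clustering, panels, deconvolution,
  evaluation, ruler, pipeline orchestration.
* `analysis/` — numbered narrative drivers over the package.
* `vignettes/mixture-deconvolution.Rmd` — the methods notes: model,
  parameter rationale, what the simulation does and does not emulate,
  numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance suites (oracle-first:
  closed forms, brute-force simplex grids, independent solver
  cross-checks).
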