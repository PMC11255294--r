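---
title: "Methods: statistics and design of the plasticore multiome toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and design of the plasticore multiome toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasticore)
```

This vignette documents the statistical models, parameter choices and
numerical conventions behind `plasticore`, in the spirit of the methods
sections of established differential-analysis packages. The package
targets paired single-nucleus RNA + ATAC data from innate lymphoid cell
(ILC) populations — where the question of interest is whether ILC2s
acquire ILC1-like character under inflammatory pressure — but every
component is generic count/interval machinery.

## Coordinate conventions

All disk formats are BED-convention: 0-based, half-open, with fragment
files following the same rule. In memory, intervals live in `GRanges`
(1-based, closed), which represents exactly the same set of bases; the
readers and writers in `io_formats` do the shift. The operational
consequence that matters is preserved everywhere: a fragment `[100,200)`
does **not** overlap a region `[200,300)`, and region merging in
`region_set_fragment_counts()` uses `min.gapwidth = 0` so book-ended
regions are never fused. Matrix Market files are 1-based on disk, as the
format requires, and gzip is auto-detected from the `.gz` extension.

## Nucleus QC

`filter_nuclei()` keeps a nucleus iff

- 1000 < total RNA counts < 25000,
- 5000 < total ATAC counts < 70000,
- mitochondrial fraction < 0.20,

with **all bounds strict**, so boundary values are removed. The
mitochondrial fraction is computed on RNA UMI counts over a designated
mitochondrial gene set; the modality and count type are a package
convention (the standard one) since QC text rarely pins them down.
`filter_min_umi()` removes cells with fewer than 200 total UMIs (exactly
200 is kept). `cap_duplicates()` keeps the first five occurrences of
each read key in input order; keys are fragment coordinates
(chrom, start, end, strand when available) — a coordinate-level proxy
for "identical sequence" that is exact for fragment data, and the key
function is the caller's to change.

## Normalization

RNA uses library-size log-normalization,
$v_{ij} = \ln(1 + s\,x_{ij}/N_j)$ with scale $s = 10^4$. This replaces
regression-based variance stabilization deliberately: the differential
tests below are rank-based, so any per-cell monotone transform of
proportions yields identical statistics, and the simpler transform keeps
the pipeline dependency-free and exactly reproducible.

ATAC peaks use TF-IDF: $\mathrm{TF}_{ij} = x_{ij}/N_j$,
$\mathrm{IDF}_i = n_{\text{cells}} / \sum_j x_{ij}$, combined as
$\ln(1 + s\,\mathrm{TF}\,\mathrm{IDF})$. Published toolchains differ in
whether the IDF is computed on binarized counts; the package default is
the non-binarized form, with `binarize_idf = TRUE` exposed, and the
method used is recorded in the output's `method` attribute. Peaks with
zero total cannot be normalized and are dropped with a warning. Natural
log is used throughout; base-2 logs appear only in reported `log2fc`
columns.

Bulk counts use median-of-ratios size factors: per sample, the median
over reference regions (positive geometric mean across samples) of the
count over the region's geometric mean. Factors are reported unscaled,
so statements about them are invariant only up to a common constant.

## Wilcoxon rank-sum testing with AUC

`rank_sum_auc()` computes $U = R_A - n_A(n_A+1)/2$ with midranks, and
the AUC $U/(n_A n_B)$, i.e. $P(X_A > X_B) + \tfrac12 P(X_A = X_B)$. For
pooled sizes $n \le 12$ the p-value is exact: all $\binom{n}{n_A}$ group
assignments are enumerated (ties included, since the enumeration works
on the observed midranks). Beyond that, a normal approximation with the
standard tie-corrected variance and a 0.5 continuity correction is used,
matching classical implementations at the sample sizes where they agree.
The complementarity $\mathrm{auc}(A,B) + \mathrm{auc}(B,A) = 1$ is exact
by construction.

`differential_features()` runs this test one-vs-rest per feature and
reports an average log2 fold change computed on de-logged normalized
values with pseudocount $\varepsilon = 10^{-9}$ on both means. For
matrices that are not log-scaled — motif deviation z-scores, which can
be negative — `delog = FALSE` switches the effect size to the difference
of group means, since a log-ratio of signed means is undefined. BH
adjustment is applied across all tested features; significance filtering
(padj < 0.05, positive effect) is left to the caller so that both
directions remain inspectable.

## Simplified negative-binomial Wald test

`nb_wald_differential()` is a deliberately compact two-group test for
replicate-level counts (bulk ATAC on a union peak set, or per-sample
gene-activity sums):

1. median-of-ratios size factors;
2. per-region method-of-moments dispersion
   $\alpha_i = (s_i^2 - \bar\mu_i)/\bar\mu_i^2$ on normalized counts,
   with $s_i^2$ computed **within condition groups** (group-centered
   residuals), so genuine between-group differences do not masquerade as
   dispersion;
3. by default, the parametric mean-dispersion trend
   $\alpha(\mu) = a_0 + a_1/\mu$ is fit across regions by OLS and the
   fitted value is used per region. With a handful of replicates the
   per-region estimate has so few degrees of freedom that testing
   against it is hopeless in both directions (anticonservative when it
   collapses to zero, powerless when inflated); the trend shares
   information across regions through two global coefficients only —
   there is no per-region empirical-Bayes blending, which stays out of
   scope. `dispersion = "per_region"` restores the raw estimates.
4. a two-group NB GLM with log link and size-factor offsets, fit by a
   damped Newton iteration on the per-group log-mean (vectorized across
   regions; convergence tolerance $10^{-10}$ on the step, maximum 50
   iterations, steps clamped to ±5 on the log scale);
5. Wald $z = \hat\beta/\mathrm{SE}$ with
   $\mathrm{SE}^2 = 1/\mathcal I_A + 1/\mathcal I_B$,
   $\mathcal I_g = \sum_{j \in g} \mu_{ij}/(1+\alpha_i \mu_{ij})$,
   two-sided normal p, BH adjustment.

All-zero regions are skipped and reported with `NA` statistics. Omitted
relative to full-scale tools, on purpose: dispersion shrinkage, outlier
(Cook's) filtering, independent filtering, and multi-factor designs.

On the package's bulk simulation (2000 regions, 3 vs 3 replicates, NB
dispersion 0.1, lognormal baseline means around 100), the acceptance
suite verifies a raw p < 0.05 fraction of about 0.05 under the null with
zero BH discoveries in at least 9 of 10 seeds, and ≥ 90% recovery of
regions planted at log2FC = 2 — the suite's measured values are near
0.054 and 98%.

## Signature scoring and rank classification

`mean_expression_score()` averages normalized expression over the
signature genes present in the matrix; absent genes are dropped (with
the found fraction attached) rather than zero-imputed, matching the
averaging-over-present-features convention. `rank_classifier()` ranks
**all** genes within each cell (midranks, ascending, so the highest
expression gets the highest rank), scores each signature by the mean
rank of its genes, and labels the cell with the arg-max signature.
Ranking across all genes rather than within the signature union makes
the score a calibrated quantile-like quantity per cell; because it is
rank-based, the labels are invariant to any strictly monotone per-cell
transform of expression. An exact tie of the two best scores (difference
≤ 10⁻¹², the `tie_tol` parameter) yields `Undetermined` — ties are
meaningful (perfectly symmetric profiles), so they are surfaced instead
of broken arbitrarily.

## Accessibility aggregation

`gene_activity_matrix()` uses strand-aware windows: gene body plus a
2-kb (`flank`) upstream extension — `[start − flank, end)` for `+`
genes, `[start, end + flank)` for `−` genes — clipped at position 0.
End-of-chromosome clipping would need chromosome sizes, which are
optional inputs the synthetic genome never requires.
`tss_window_signal()` places the TSS at the body start (`+`) or end
(`−`) and spans 300 bp upstream to 500 bp downstream in gene
orientation. Both window conventions are exposed as parameters because
published descriptions of promoter windows are frequently inconsistent
about orientation; the defaults follow the −300/+500 convention.

`per_cell_region_score()` TF-IDF-normalizes a region-count matrix and
averages over **all** regions of the set per cell (not only nonzero
ones — the zeros carry signal about absent accessibility).
`lineage_specific_sets()` z-scores differential features across groups,
clusters with average-linkage hierarchical clustering on Euclidean
distances, cuts at `k`, and assigns each cluster to its maximal-mean
group; average linkage + Euclidean on z-scores is the package's choice
where "hierarchical clustering" alone underdetermines the procedure.
Features with zero variance across groups are an error, not silently
dropped.

## Motif deviations

For motif $m$ and cell $c$:
$\mathrm{raw}_{mc} = (o_{mc} - e_{mc})/e_{mc}$ with
$e_{mc} = N_c \sum_{p \in m} t_p / T$, where $t_p$ is the peak's total
count and $T$ the grand total. The z-score standardizes raw deviations
against `n_background = 50` size-matched background peak sets, each
drawn (with replacement, deterministically under the seed) from the
peak's own bin after binning all peaks by log mean accessibility into
`n_bins = 50` bins — and by GC fraction on a 2-D grid when the motif map
supplies one. Matching on accessibility alone is the default because
synthetic peaks carry no sequence; the GC dimension engages
automatically when present. Motifs with zero expected counts are dropped
with a warning rather than emitting NaN rows. Two exact invariants hold
by construction and are enforced in tests: a motif containing every
peak has raw deviation 0 in every cell, and deviations are invariant to
multiplying all counts by a constant.

## Regulator ranking

`candidate_regulators()` joins per-TF differential expression with
differential motif deviation via an explicit gene↔motif map, applies the
four-part filter (RNA padj < 0.05 ∧ RNA log2FC > 0 ∧ motif padj < 0.05 ∧
motif Δ > 0) and ranks passing TFs by the mean of the two AUCs. Because
deviation z-scores are signed, the "motif fold change" is implemented as
the difference of group means; the AUC is unaffected by that choice.
Filtering before averaging and averaging before filtering order passing
TFs identically, so the package filters first. Ties break by RNA AUC,
then lexical gene ID — a documented, deterministic order. A gene mapped
to several motifs keeps its best-scoring pair.

## Patient-pool scoring

`score_patient_samples()` counts fragments per nucleus at the region
set within each sample, merges the matrices across samples, and TF-IDF
normalizes the **merged** matrix so scores are comparable across
samples (per-sample normalization is available via `normalize =
"none"` plus manual processing). Nuclei with no fragments at the set
cannot be normalized and are dropped with a warning.
`compare_conditions()` treats nuclei as independent observations in the
categorical OLS model — the convention of the workflows this mirrors —
while the per-sample summary table supports a means-based re-analysis
for users concerned about pseudoreplication. The display subset per
sample is the top `ceil(0.9 n)` scores, matching violin displays that
trim the bottom decile. Both a full condition grouping and a collapsed
grouping (via a named map) are supported, and size-matched random
control sets come from `sample_control_regions()` (uniform, without
replacement, seeded).

## The synthetic multiome generator

`generate_multiome()` plants recoverable structure for every downstream
stage:

- RNA: negative binomial with variance $\mu + \alpha\mu^2$
  (`rna_dispersion` α = 0.5), baseline mean 2 per gene, per-cell
  log-normal library factors (`libsize_sigma` = 0.3, unit mean), and a
  4-fold (`rna_effect`) boost of each type's 50 signature genes in its
  own cells. Mitochondrial genes (10) receive means tuned so the
  expected mitochondrial fraction is `mito_fraction_mean` = 0.05.
- ATAC: Poisson peak counts (sparse ATAC counts are near-binary at the
  per-cell level) with baseline rate 0.2 and a 3-fold (`atac_effect`)
  boost of each type's 100 signature peaks.
- Fragments: one record per count unit, placed uniformly inside the
  peak on a synthetic genome (one chromosome per 1000 peaks, 500-bp
  peaks spaced 2 kb apart; gene j is a 2-kb body centred on peak j with
  alternating strand). Counting fragments back over the peak set
  reproduces the ATAC matrix exactly — a tested identity.
- Motifs: 60 motifs of 50 peaks; the planted regulator draws 80%
  (`regulator_overlap`) of its peaks from the last type's signature
  peaks and is paired with a gene inside that type's RNA signature; the
  59 decoys sample non-signature peaks.

Effect sizes are package choices — chosen once as values a practitioner
would call a strong but realistic cell-type signal — since the workflows
this emulates do not publish their underlying effect magnitudes. A
single integer seed expands into per-component substreams (RNA, ATAC,
fragments, motifs), so each component is individually reproducible and
no global RNG state leaks between stages.

`generate_bulk_counts()` produces NB counts with lognormal baselines
(log-mean log(100), log-sd 0.7), lognormal size factors (σ = 0.2), NB
dispersion 0.1 — a typical biological-replicate ATAC setting — and the
first `n_differential` regions shifted by `planted_log2fc` in condition
B. `generate_patient_pools()` gives each nucleus its condition's
probability of being signature-positive (3-fold fragment-rate boost in
signature regions), with all nuclei sharing background rates; depth is
the expected fragment count of a negative nucleus.

What the generator does **not** emulate — and what passing tests
therefore do not certify on real data: doublets, ambient contamination,
batch effects, realistic sequence content and GC bias, peak-calling
artefacts, and cross-modality correlation structure beyond the shared
cell labels.

## Problem sizes and reproducibility

The test and acceptance workloads use 2 × 300 cells, 1000 genes, 2000
peaks for the multiome; 2000 regions × (3 + 3) replicates × 10 seeds for
bulk calibration and recovery; and 3 conditions × 2 samples × 100 nuclei
for patient pools — sizes at which every statistical contract in the
acceptance suite is stable across seeds while the full suite runs in
well under a minute per stage. All stochastic steps take explicit
integer seeds, and `run_pipeline()` records seeds, parameters and
per-stage dimensions in its JSON manifest; identical configurations
produce byte-identical outputs.

## Known limitations

- The NB Wald test supports exactly two conditions and a single-factor
  design; no shrinkage, outlier handling or independent filtering.
- Classification is signature-based only; reference-based label
  transfer via dataset integration is out of scope.
- Gene windows clip at position 0 but not at chromosome ends unless
  sizes are supplied.
- TF-IDF scores depend on the cell population in the matrix (through
  IDF and, after merging, through all samples), so scores are
  comparable only within one normalized matrix.
- The duplicate cap operates on fragment coordinates, not sequences.
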