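---
title: "Methods: tissue-specific expression, promoter methylation, and region-restricted EWAS"
author: "tsmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific expression, promoter methylation, and region-restricted EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmeth)
```

# The analysis model

`tsmeth` links three layers of data collected on matched samples from
several tissues: a gene annotation, a gene × sample TPM expression matrix,
and per-CpG whole-genome bisulfite methylation calls; a fourth, independent
layer is a case/control methylation-array cohort. The scientific question
is whether promoter methylation of tissue-specific genes tracks their
expression, and whether the CpGs of those promoters carry disease
associations.

## Promoter windows

All promoter windows are anchored on a single representative transcript per
gene: the transcript whose TSS is 5′-most in transcription direction, with
ties broken by lexicographically smallest transcript id. Gene annotations
rarely say which isoform "owns" the promoter; anchoring on the most
upstream TSS is a fixed, reproducible convention and is applied uniformly.

Internally, regions are held as `GRanges` (1-based closed coordinates, the
Bioconductor convention); every on-disk interchange of regions uses BED,
which is 0-based half-open, and `rtracklayer` performs the conversion. With
a 1-based TSS $t$ on the plus strand:

* **proximal** = $[t-200,\; t+49]$ — 200 bases strictly upstream, the TSS
  base, and 49 further downstream bases, 250 bp in total. The window is
  stated in the literature as offsets ("200 up / 50 down") without an
  inclusivity convention; this package fixes the 250 bp reading and
  documents it.
* **typical** = $[t-2000,\; t-1]$ — the 2 kb immediately upstream (2000 bp).
* **expanded** = $[t-2000,\; \text{end of first intron}]$. First-intron
  methylation correlates with expression in both directions, which
  motivates extending the association window into the gene.

Minus-strand genes mirror these windows in transcription direction, and all
coordinates clip at the chromosome start (so span invariants hold except
under clipping). A single-exon representative transcript has no first
intron; its expanded region runs to the transcript 3′ end and is flagged
`no_first_intron` rather than failing.

## Tissue specificity (Tau)

Tau is computed on **linear** per-tissue mean TPM:
$$\tau = \frac{\sum_{i=1}^{n}(1-\hat x_i)}{n-1},\qquad
  \hat x_i = \frac{x_i}{\max_j x_j}.$$
It is 0 for a uniform profile, 1 for single-tissue expression, scale
invariant, and bounded in $[0,1]$ for any non-negative profile with a
positive maximum. Genes enter the Tau analysis only if their TPM reaches 1
in at least one sample (`filterExpressed(mode = "max_ge_one")`, boundary
kept at exactly 1); genes are called tissue-specific at τ ≥ 0.8 (boundary
inclusive) and assigned to the arg-max tissue. An exact arg-max tie is
broken by the fixed tissue order (order of first appearance in the sample
sheet) and flagged, so downstream results are reproducible rather than
platform-dependent. Log-scale Tau is deliberately not the default: the mean
TPM profile is used as-is, which weighs the dominant tissue more strongly.

## Expression processing

The only transform applied is $\log_2(\mathrm{TPM}+1)$ — the most common
transcriptomics convention; zeros map to zero and the transform is
monotone. Pairwise sample correlations (quality control) default to the
log scale. Batch adjustment is intentionally out of scope: the sample sheet
carries a `batch` column and the simulator can be extended with batch
shifts, but removing them is left to dedicated tools.

## Methylation aggregation

Per-CpG calls are accepted in BSMAP-ratio style TSV (chrom, 1-based
position, strand, context, methylation ratio, effective coverage) or as
4-column bedGraph. The depth filter keeps calls with coverage ≥ 10
(inclusive); bedGraph input has no coverage column, so the filter is
skipped with a warning. A record whose ratio falls outside $[0,1]$ is
rejected individually with a diagnostic rather than poisoning the file.

A promoter's methylation level in a sample is the **unweighted** arithmetic
mean of the ratios of the CpGs inside the region ("the average of all the
promoter methylation levels"); coverage weighting is available behind the
`weighted` flag for users who prefer pooled-read semantics. Plus- and
minus-strand cytosines are independent records — no CpG-dyad merging, since
per-cytosine ratio files do not guarantee dyad pairing. Cells with fewer
than `min_cpgs` (default 1) contributing CpGs are missing, not zero.

## Expression–methylation integration

Per gene, Pearson's r between log expression and proximal-promoter
methylation is computed across **all matched samples pooled over tissues**:
the tissue contrast is the signal of interest, and per-tissue correlations
at these sample sizes would be dominated by noise. Missing methylation
cells are removed pairwise; r is undefined below `min_pairs = 10` complete
pairs or when either variable is constant. Classification is boundary
inclusive: $r \le -0.3$ negative, $r \ge 0.3$ positive, otherwise none.

K-means clustering (k = 5 by default) operates on rows z-scaled per gene,
making assignments invariant to per-gene affine transforms; the objective
is standard Euclidean inertia with 10 random restarts and a mandatory seed.
When k equals the number of genes the zero-inertia singleton assignment is
returned directly (the Hartigan–Wong search does not handle that edge).
Rows are ordered within clusters by average-linkage hierarchical clustering
on $1 - r$ (Pearson) distance; columns are grouped by tissue label — a
supervised axis, not inferred structure.

## Enrichment

EnrichR-style web services are replaced by a local one-sided hypergeometric
upper-tail test per gene set against a user-declared background, with
Benjamini–Hochberg adjustment across sets. The query must be a subset of
the background; offenders are listed. This is a standard Fisher-one-sided
equivalent, and external combined scores are not reproduced.

## Region-restricted EWAS

Probes are restricted to the expanded promoters of one tissue's TSGs
(default `adipocyte`); a probe hit by several genes' regions is tested once
with all gene attributions recorded. The association model is a **linear
regression of the beta value on the case indicator plus covariates**
(methylation-as-response, the dominant EWAS convention), with a two-sided
Wald p on the case coefficient; logistic (status-as-response) and M-value
($\log_2 \beta/(1-\beta)$, β clipped to $[10^{-3}, 1-10^{-3}]$) variants
are available behind flags since the original model family is a genuinely
open choice. Covariates default to age and sex; the secondary-trait (T2D)
analysis adds BMI. Missing covariates drop samples listwise; constant
probes are flagged, not fatal.

Discovery significance is Bonferroni: $p \le \alpha/m$ with $m$ the number
of probes actually tested. Replication requires nominal $p < 0.05$ **and**
effect-direction concordance; the concordance requirement goes beyond a
bare nominal-p criterion but is standard practice, and can be switched off
(`require_concordance = FALSE`) to recover the literal rule.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, at
desk scale, with every parameter exposed in `simConfig()`:

| parameter | default | role |
|---|---|---|
| tissues × samples | 5 × 10 | matched design (a 52-sample, five-tissue study is the template) |
| gene classes | 40 / 20 / 140 | negative-coupled, positive-coupled (2:1), null |
| expression | μ_on = 6, μ_off = 0.5, μ_null = 3, σ = 0.5 | log2(TPM+1) scale |
| promoter coupling | Beta(2,18) vs Beta(18,2) | hypo- ≈ 0.10 vs hyper-methylated ≈ 0.90 state |
| typical baseline | Beta(8,12) | uncoupled, mean 0.40 — chosen above the proximal baseline so the proximal < typical contrast holds |
| per-CpG jitter | sd 0.03, clipped to [0,1] | local CpG heterogeneity |
| CpGs per promoter | 8 | aggregation support |
| coverage | Poisson(30) | so the depth ≥ 10 filter bites rarely |
| single-exon genes | 5 % of null genes | exercises the degenerate expanded-promoter path |
| EWAS cohorts | 200/250 discovery, 337/422 replication | the 450-sample discovery and 759-sample replication design; the replication split is not published, so it is kept proportional to discovery |
| probes / planted DMPs | 500 / 3 | Δβ = 0.08 on a Beta base with mean 0.5, sd 0.05 |
| covariates | age ~ N(50, 8), sex ~ Bern(0.5) | BMI ~ N(31.6, 1.6) cases / N(21.4, 1.1) controls |

Gene models are written on one synthetic chromosome as two-exon transcripts
(exon 200 bp, intron 300 bp, exon 500 bp, genes 8 kb apart) so proximal,
typical and expanded windows never collide between neighbours. Both
generators are fully deterministic given the seed, to the byte, and their
output files round-trip through the package's own readers without warnings.

An optional confounding mode makes age shift both the case probability and
every probe's beta value; contrasting adjusted against unadjusted analyses
on such a cohort demonstrates that the covariate adjustment, not the model
family, carries the calibration.

**What the simulator does not emulate** — and therefore what passing tests
do *not* establish about real data: read-level noise and mapping artefacts,
CpG co-methylation / LD-like correlation between probes, array probe
chemistry and normalization effects, batch structure, cell-type
heterogeneity within tissues, and genuine biological effect-size
distributions (planted effects are homogeneous). Recovery rates on
synthetic data validate the pipeline's logic and thresholds, not the power
of any particular real study.

# Numerical choices and degenerate inputs

* Thresholds are boundary-inclusive where stated: TPM = 1 is kept,
  τ = 0.8 is a TSG, |r| = 0.3 is classified, coverage 10 is kept;
  replication uses strict p < 0.05.
* All-zero expression profiles make Tau's normalization undefined: they are
  an error in `computeTau` and an `NA`-with-warning in the vectorized
  `callTSGs`.
* Zero-variance samples (expression QC), genes (clustering, correlation)
  and probes (EWAS) are excluded with warnings or flags, never silently
  imputed; no imputation is performed anywhere (pairwise deletion for
  correlation, complete rows for clustering, listwise deletion for
  covariates).
* `bonferroniThreshold(0.05, 4443)` = 1.1254 × 10⁻⁵, printed as
  1.13 × 10⁻⁵ at three significant figures.
* The per-probe linear model is solved once through the shared hat matrix
  (the design is identical across probes), which matches `stats::lm`
  coefficient-for-coefficient (asserted in the tests to 10⁻¹⁰) at a
  fraction of the cost.

# Problem sizes in the test suite

The packaged tests run the full default simulation (200 genes × 50 samples,
~3,200 CpGs per sample; 500 probes × 450 + 759 array samples) for the
recovery checks, and reduced configurations (10–40 genes, 2–6 samples per
tissue) for contract tests — sizes chosen so the whole suite completes in a
few minutes on a laptop while keeping every recovery margin wide. The null
calibration check uses 1,000 independent null probes at n = 100, giving a
binomial standard error of ~0.7 percentage points around the nominal 5 %.

# Known limitations

* One representative transcript per gene: alternative-TSS genes get a
  single promoter; isoform-resolved analysis is out of scope.
* The enrichment test assumes an exchangeable background; no gene-length or
  expression-level bias correction is applied.
* The EWAS stage does not perform array preprocessing, cell-type
  deconvolution, or genomic-inflation correction; inputs are assumed to be
  cleaned beta matrices.
* Catalog-based "novel vs known" annotation of validated CpGs requires
  external databases and is left to the user (the output schema carries the
  columns).
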