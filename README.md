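# tsmeth

Integrated analysis of tissue-specific gene expression and promoter DNA
methylation across matched multi-tissue samples, with a downstream
region-restricted epigenome-wide association study (EWAS).

## What it is for

In multi-tissue studies that pair RNA-seq with whole-genome bisulfite
sequencing (WGBS) of the same samples, a recurring question is whether the
promoter methylation of a tissue-specific gene (TSG) tracks — usually
opposes — its expression, and whether the CpGs in those promoters associate
with disease phenotypes in independent methylation-array cohorts. `tsmeth`
implements that analysis as a tested, reusable R pipeline for epigenomics
researchers:

1. **Promoter derivation** — strand-aware windows anchored on each gene's
   representative transcription start site (TSS), parsed from a
   GENCODE-like GTF:
   * *proximal*: 200 bp upstream through 49 bp downstream of the TSS
     (250 bp);
   * *typical*: the 2 kb immediately upstream;
   * *expanded*: 2 kb upstream through the end of the first intron.
2. **Tissue specificity** — the Tau statistic on per-tissue mean TPM,

   τ = Σᵢ (1 − x̂ᵢ) / (n − 1),  x̂ᵢ = xᵢ / maxⱼ xⱼ,

   ranging from 0 (ubiquitous) to 1 (single-tissue); genes with τ ≥ 0.8 are
   called TSGs and assigned to their highest-expressing tissue.
3. **Methylation aggregation** — per-CpG WGBS calls (depth ≥ 10) averaged
   over each promoter region per sample.
4. **Integration** — per-gene Pearson correlation between log₂(TPM+1)
   expression and proximal-promoter methylation across all matched samples;
   genes with |r| ≥ 0.3 are classified as negatively or positively coupled,
   and coupling patterns are clustered by row-scaled K-means (k = 5).
5. **Enrichment** — a local hypergeometric over-representation test of gene
   lists against user GMT collections, BH-adjusted.
6. **EWAS** — array probes restricted to the expanded promoters of the
   TSGs of one tissue, tested by linear regression of beta values on
   case/control status with covariates (age, sex; BMI for the secondary
   trait), Bonferroni discovery (α/m), and independent replication at
   nominal p < 0.05 with effect-direction concordance.

A synthetic-data module (`simulateMultiomics`, `simulateEwasCohort`)
generates all of the above with planted, recoverable truth, so the entire
pipeline can be exercised and validated without controlled-access data.

## Worked example

Generate a synthetic five-tissue cohort (10 matched samples per tissue;
40 negatively coupled TSGs, 20 positively coupled, 140 null genes) and run
the whole pipeline from one config:

```r
library(tsmeth)

cfg <- simConfig(seed = 1)
simulateMultiomics(cfg, out_dir = "demo")

report <- runPipeline(list(
  gtf = "demo/genes.gtf",
  expression = "demo/expression.tsv",
  sample_sheet = "demo/sample_sheet.tsv",
  calls_dir = "demo/calls",
  seed = 1, out_dir = "demo/out"))

report
#> AnalysisReport
#>   TSGs (tau >= 0.8 ): 60
#>   correlated genes: 60 (40 negative / 20 positive)

report$direction_summary
#>      tissue negative positive
#>   adipocyte        8        4
#>  fibroblast        8        4
#>       islet        8        4
#>      kidney        8        4
#>         smc        8        4
#>       Total       40       20
#> 60 correlated genes: 40 negative (67%), 20 positive

round(report$meth_summary_pct, 1)
#> proximal  typical
#>     26.2     33.4

report$sample_correlation
#> Pairwise sample correlation over 50 samples
#>   mean within-tissue r:  0.884
#>   mean between-tissue r: 0.016
```

All 60 planted TSGs are recovered at τ ≥ 0.8 and every one falls on the
planted coupling side of the |r| ≥ 0.3 threshold; proximal promoters come
out hypomethylated relative to typical promoters; samples of the same
tissue correlate far more strongly than samples of different tissues —
the qualitative structure the analysis is designed to detect. The per-tissue
direction table's column sums are checked against its `Total` row (the
accounting identity used throughout the summary report).

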