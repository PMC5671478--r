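# stableref

Reference-gene (housekeeping-gene) discovery and validation from
transcriptome and RT-qPCR data.

Quantitative gene-expression analysis — RT-qPCR above all — stands or falls
with the internal controls used to normalize it. The genes traditionally used
as controls (actin, tubulin, ubiquitin, EF1α, 18S rRNA, ...) are often not
stably expressed in a given tissue/treatment system, and many of them have
multiple splice isoforms that primers cannot distinguish. `stableref`
implements the alternative: mine an RNA-seq expression matrix for transcripts
that are *demonstrably* stable in the system at hand, validate candidates with
the standard RT-qPCR stability algorithms, and then use the winners to
normalize expression data. It is aimed at molecular biologists and
bioinformaticians who have a transcripts × samples expression table (FPKM or
counts) and/or a genes × samples Cq table and need defensible reference genes.

## What it computes

**Genome-wide screening** of an expression matrix, per transcript:

- CV = 100 · SD/mean of expression across all samples (sample SD, n−1);
- MFC = max/min of expression across samples;
- |CV| of log2-transformed expression;
- a constitutive flag (detected, i.e. > 0, in every sample).

A transcript is *stable* when it is constitutive, MFC < 2, and either
CV < 20% or |CV(log2 FPKM)| < 5%. Recommended reference candidates
additionally need a mean expression inside a practical window (default
50–1000 units) and a unique isoform per the annotation (GTF).

**RT-qPCR stability ranking** of a candidate Cq panel, after assay QC
(efficiency > 1.8, calibration R² > 0.99, all Cq < 40):

- **geNorm**: M = mean SD of pairwise log2 expression ratios, with stepwise
  exclusion, plus the pairwise-variation curve V(n, n+1) and the optimal
  number of reference genes (cutoff V < 0.15);
- **NormFinder**: model-based intra-group variance + shrunken inter-group
  bias on the log2 (−Cq) scale;
- **BestKeeper**: dispersion of raw Cq (mean absolute deviation), with the
  per-sample geometric-mean index and each gene's correlation to it;
- **comparative ΔCt**: mean SD of pairwise Cq differences;
- a **consensus**: the geometric mean of the four ordinal ranks, ranked
  ascending.

**Reference-gene normalization and DE calling**: per-sample normalization
factors as the geometric mean of the chosen reference genes, fold change of
normalized group means, calls at FC > 2 (up) / FC < 0.5 (down), and a
concordance summary against an external DE table.

**Synthetic data generators** with known ground truth (stable / variable /
condition-specific / silent transcripts; stable vs noisy/shifted Cq genes)
emulating a 2-tissue × 2-treatment × 3-replicate design, so the whole
pipeline is testable end to end.

## Worked example

Simulate a 15-gene Cq panel (3 truly stable genes, 2 groups × 6 samples) and
rank it:

```r
library(stableref)
library(tibble)

sim   <- simulate_cq(seed = 101)
panel <- rank_stability(sim$cq, sim$design)
head(as_tibble(panel), 5)
#> # A tibble: 5 × 11
#>   gene   bestkeeper_value bestkeeper_rank deltact_value deltact_rank
#>   <chr>             <dbl>           <int>         <dbl>        <int>
#> 1 gene15           0.0696               1          1.08            1
#> 2 gene09           0.0717               2          1.08            2
#> 3 gene07           0.0736               3          1.08            3
#> 4 gene04           0.480                4          1.22            4
#> 5 gene14           0.709                5          1.35            5
#>   genorm_value genorm_rank normfinder_value normfinder_rank geomean final_rank
#>          <dbl>       <int>            <dbl>           <int>   <dbl>      <int>
#> 1        0.128           2            0.168               2    1.41          1
#> 2        0.128           1            0.177               3    1.86          2
#> 3        0.148           3            0.159               1    2.28          3
#> 4        0.665           4            0.222               4    4             4
#> 5        0.882           5            0.461               5    5             5

glance(panel)
#> # A tibble: 1 × 7
#>   n_genes n_samples optimal_n v_flag final_m best_gene best_geomean
#>     <int>     <int>     <int> <chr>    <dbl> <chr>            <dbl>
#> 1      15        12         2 ok       0.128 gene15           1.41

sim$truth$gene[sim$truth$stable]
#> [1] "gene07" "gene09" "gene15"
```

The three truth-stable genes occupy the consensus top 3: every column pair
`<method>_value` / `<method>_rank` is one stability algorithm (smaller =
more stable), `geomean` is the consensus score, and `glance()` reports that
two reference genes suffice (`optimal_n = 2`, all pairwise variation below
0.15). `autoplot(panel)` draws the rank comparison;
`autoplot(attr(panel, "genorm_fit"), type = "v")` the V curve.

The genome-wide screen works the same way on an expression matrix:

```r
fpkm  <- simulate_fpkm(seed = 1)
stats <- transcript_stats(fpkm$matrix)
screen_report(select_stable(stats))   # counts + percentages
recommend_references(stats, require_unique_isoform = FALSE)
```

A YAML-configured end-to-end run (screen → qpcr → normde) is available as
`run_pipeline("pipeline.yaml")`, with a thin CLI in
`inst/scripts/stableref.R`.

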