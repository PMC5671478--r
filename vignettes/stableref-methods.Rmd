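---
title: "Reference-gene selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stableref)
```

`stableref` covers three linked tasks: screening a transcriptome expression
matrix for stably expressed transcripts, ranking RT-qPCR candidate genes with
the four standard stability algorithms plus a rank consensus, and using chosen
reference genes to normalize expression data for fold-change based
differential-expression calls. This vignette explains the statistics, the
tunable parameters, and the choices made where conventions in the field
diverge.

## The genome-wide screen

For each transcript with expression values $x_1,\dots,x_n$ over $n$ samples,
`transcript_stats()` computes

* $\mathrm{CV} = 100\,s/\bar x$ (percent), with $s$ the sample SD
  ($n-1$ denominator);
* $\mathrm{MFC} = \max_i x_i / \min_i x_i$, defined only when the transcript
  is detected in every sample;
* the constitutive flag: $x_i > t$ in all samples ($t$ =
  `detect_threshold`, default 0 — "detected at all");
* $|\mathrm{CV}|$ of $\log_2 x$, again only for constitutive transcripts.

`select_stable()` keeps a transcript when it is constitutive, MFC < 2, and
either CV < 20% **or** $|\mathrm{CV}(\log_2 x)| < 5\%$. The log clause exists
because the two scales disagree: CV on the raw scale penalizes proportional
noise at high expression, while the log-scale CV is dominated by the log-mean
denominator and behaves differently for transcripts near 1 expression unit.
The thresholds are exposed (`cv_max`, `mfc_max`, `logcv_max`); a relaxed
screen with `cv_max = 30` is common when the 20% rule proves too strict for
genes later shown stable in RT-qPCR.

Choices a reader should know about:

* **SD denominator.** The sample ($n-1$) SD is the default; `sd_denom = "n"`
  gives the population form. With $n = 12$ samples the difference is ~4% of
  the CV, which matters only for transcripts sitting exactly at a threshold.
* **MFC scope.** The max/min ratio is taken across individual samples (the
  stricter reading) rather than across condition means;
  `mfc_scope = "group_mean"` provides the latter.
* **Log base.** Base 2 by default (`log_base` accepts 10 or `exp(1)`). The
  filter uses the *absolute* CV of the log values because the log-mean can be
  negative for expression below one unit.
* **No pseudocount by default.** The constitutive filter guarantees positive
  values wherever a log is taken; `pseudocount` exists for count matrices
  where zeros should be retained rather than treated as "not detected".
* **Ties.** All rankings order by the metric, then by transcript id, so
  results are deterministic.

`recommend_references()` adds the two practical criteria: a mean expression
window (`expr_min = 50`, `expr_max = 1000` by default; 100–1000 is a common
stricter alternative — too low is hard to quantify, too high wastes dynamic
range and reagents) and isoform uniqueness from a GTF-derived index, because
isoforms of one gene can differ hugely in level and stability and primers
often amplify several isoforms at once. `top_overlap()` quantifies the
consistency of alternative stability metrics (e.g. CV of FPKM vs CV of
counts vs CV of log FPKM) as the overlap fraction of their top-$n$ lists; the
screen itself is threshold-driven, with top-$k$ selection available through
this comparison path.

## RT-qPCR stability algorithms

Candidates first pass `qc_candidates()`: amplification efficiency
$E > 1.8$ (per-cycle amplification factor; 2 is perfect doubling),
calibration $R^2 > 0.99$, and every Cq < 40. Efficiencies are inputs
(estimated upstream, e.g. from fluorescence curves); the package does not
re-derive them.

All algorithms require complete Cq rows; genes with missing cells are dropped
with a logged reason. Replicate wells in long-format input are averaged
arithmetically on the Cq scale (the field convention; at fixed efficiency it
is identical to the geometric mean of the implied quantities, which
`read_cq_table()` also exposes as an explicit mode).

**geNorm** (`genorm()`) works on relative quantities
$q_{gs} = E_g^{\,\min_{s'} \mathrm{Cq}_{gs'} - \mathrm{Cq}_{gs}}$, so the
best sample of each gene has $q = 1$. Pairwise variation
$V_{jk} = \mathrm{SD}_s[\log_2(q_{js}/q_{ks})]$; stability
$M_j = \mathrm{mean}_{k \ne j} V_{jk}$ within the current gene set. The gene
with the largest $M$ is removed (ties: the lexicographically larger id goes
first, consistent with "value, then id" ranking) and $M$ recomputed until two
genes remain; a gene's reported value is its $M$ at exclusion, the final pair
shares the final $M$. The default transform assumes $E = 2$ for every gene;
per-gene efficiencies are an option (`genorm_use_efficiencies` in
`rank_stability()`). The pairwise-variation curve uses normalization factors
$NF_n$ = per-sample geometric mean of the $n$ best genes' quantities and
$V_{n,n+1} = \mathrm{SD}_s[\log_2(NF_n/NF_{n+1})]$; the optimal number of
reference genes is the smallest $n \ge 2$ with $V < 0.15$. When every $V$ is
already below the cutoff the answer is 2 (flag `all_below`); when none is,
the package still reports 2 but flags `none_below` rather than inventing a
number.

**Comparative ΔCt** (`delta_ct()`): gene $j$'s stability is
$\mathrm{mean}_{k \ne j}\,\mathrm{SD}_s(\mathrm{Cq}_{js} - \mathrm{Cq}_{ks})$.
With $E = 2$ this is algebraically identical to the full-panel geNorm $M$
(both are mean pairwise SDs of log2 ratios), a property the test suite
verifies to $10^{-9}$ on random panels — the two methods differ only through
geNorm's stepwise exclusion.

**BestKeeper** (`bestkeeper()`): dispersion of raw Cq per gene. The default
is the mean absolute deviation from the arithmetic mean, matching the classic
spreadsheet tool's "SD [±CP]" output; a textbook $n-1$ SD is available via
`dispersion = "sd"`. Genes with dispersion > 1 cycle are flagged
inconsistent. The BestKeeper index (per-sample geometric mean of Cq) and each
gene's Pearson correlation with it are reported but deliberately not ranked
on — the ranking uses dispersion only.

**NormFinder** (`normfinder()`) treats $-\mathrm{Cq}$ as log2-scale
expression (one cycle = one doubling; an efficiency-corrected transform is a
possible extension, not the default). Within each group $g$, expression is
centred per sample across the $k$ genes, giving residuals $z_{igj}$; the
per-gene variance estimate is
$\hat\sigma^2_{ig} = \max\{0, [v_{ig} - \sum_{i'} v_{i'g}/(k(k-1))]\,k/(k-2)\}$
with $v_{ig}$ the sample variance of $z_{igj}$ over samples. Group effects
$d_{ig} = \bar z_{ig\cdot}$ are shrunk towards zero by
$b_{ig} = (d_{ig}-\bar d_i)\,\hat\gamma^2/(\hat\gamma^2 + \hat\sigma^2_{ig}/n_g)$,
where $\hat\gamma^2$ is the (floored) excess of the observed between-group
spread over its sampling noise. Stability is
$\rho_i = \mathrm{mean}_g(|b_{ig}| + \sqrt{\hat\sigma^2_{ig}/n_g})$; without
groups, $\rho_i = \hat\sigma_i$ from the single-group decomposition. The
$k/(k-2)$ correction needs $k \ge 3$ genes, and the grouped model needs at
least two groups of at least two samples. Both the grouped and ungrouped
modes exist because published consensus rankings do not always state which
was used; the tests pin the implementation to an independent loop-wise
evaluation of exactly these formulas.

**Consensus** (`consensus_rank()`): the geometric mean of each gene's four
ordinal ranks, re-ranked ascending. The engine always *produces* strict
ordinal ranks (value, then id) — shared ranks make geometric means ambiguous —
but *accepts* externally supplied rank tables that contain ties, since
published reports often print them.

## Reference-gene normalization and DE calls

`normalization_factors()` is the geometric mean of the chosen reference
genes' expression per sample; it requires every reference to be strictly
positive everywhere (a reference that disappears in a sample is a
contradiction, not a data point). `relative_de()` divides each sample by its
factor, averages per group (arithmetic mean by default; geometric available),
and calls up/down at strictly FC > 2 / FC < 0.5. Because each sample's factor
absorbs any per-sample rescaling, the calls are invariant to global and
per-column scale — the property that makes this a between-sample normalizer —
and any reference gene tested against itself gives FC = 1 exactly. Genes with
a zero control mean get `fc = NA` and an `ns` call with a warning: a ratio
against trace expression is meaningless, and such genes are exactly where
ratio-based re-evaluation and count-based DE pipelines disagree.
`concordance()` tabulates agreement with an external DE table as same-call /
same-direction-different-magnitude / discordant. No dispersion estimation or
FDR computation is attempted; this module is deliberately the simple
ratio-based re-evaluation.

## Synthetic data: what it emulates, what it does not

`simulate_fpkm()` emulates the screening substrate: a 12-sample,
4-group (2 tissues × infected/control, 3 replicates) design with five
transcript classes — `stable_high` (50–1000 units, target CV 5%),
`stable_low` (0.1–0.9 units, CV 8%), `variable` (CV 60%),
`condition_specific` (zeroed in one group), and `silent` (all zero).
Expression noise is log-normal with $\sigma$ solved from
$\mathrm{CV}^2 = e^{\sigma^2}-1$, the natural multiplicative error model for
FPKM; stable-class deviations are clamped at $\pm\log(\texttt{mfc\_cap})/2$
so the *true* fold change respects the cap (1.5 by default, safely under the
MFC < 2 filter). With CV 5% the clamp sits at ~4 standard deviations, so the
empirical CV still converges to the target (verified at $n = 200$ samples
within ±10% relative).

`simulate_cq()` emulates a validation panel: 15 genes over 2 groups × 6
samples by default, Cq = base + group shift + $N(0, \sigma)$ with
$\sigma = 0.1$ cycles for the 3 truth-stable genes and $1.0$ cycles plus a
±1.5-cycle per-group shift for the rest — additive Gaussian noise on the
cycle scale being the standard qPCR error model. Base Cq is uniform on
18–32, keeping all values inside the quantifiable range. Which genes are
stable is drawn from the seed so that id-based tie-breaking cannot favour
them. Under these defaults the consensus top 3 contains at least two
truth-stable genes in well over 90% of seeds, and the expression screen
recovers over 95% of truth-stable transcripts — both checked in the test
suite (100 and 50 seeds respectively).

What the generators do *not* model: library-size and gene-length biases of
FPKM, overdispersed counts, correlated transcripts (co-regulation), isoform
structure, batch effects, or efficiency drift between plates. Passing the
recovery tests therefore demonstrates the algorithms' correctness and the
pipeline's wiring, not that any particular threshold is optimal for real
tissue data.

## Numerical and policy details

* Quartiles use linear interpolation (R's default type 7), so the
  interquartile range of (1, 2, 3, 4) is 1.5.
* Zero-variance panels are legal: all stability values are 0 and rankings
  fall back to gene id.
* `consensus_rank()` errors when methods cover different gene sets rather
  than silently intersecting.
* Threshold comparisons are strict throughout (CV < 20, MFC < 2, FC > 2,
  efficiency > 1.8, Cq < 40, V < 0.15), matching how the rules are stated in
  practice; boundary cases therefore fail the filter.
* Test problem sizes: oracle checks run on panels of 3–8 genes and 4–12
  samples over 100–200 seeds; recovery experiments use the default generator
  shapes above. These sizes make every property cheap to recompute from
  scratch while covering the combinatorics (ties, exclusions, group shapes)
  that matter.

## Limitations

* Efficiencies and calibration $R^2$ are trusted inputs; there is no
  fluorescence-curve processing.
* The screen assumes one row per transcript id; gene-level aggregation is the
  caller's choice.
* The DE module is ratio-based by design — no significance testing. Use a
  count-based DE package when replicate-level inference is needed.
* Published consensus rankings that used unstated tie orders cannot always be
  reproduced rank-for-rank; the package exposes its tie policy instead of
  guessing others'.
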