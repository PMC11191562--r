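---
title: "macroCRE: methods and modeling choices"
author: "macroCRE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{macroCRE: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroCRE)
```

# Overview

macroCRE links paired single-cell RNA and ATAC profiles (a "multiome")
to GWAS genetics. The pipeline has five stages:

1. **CRE discovery** — peaks whose accessibility correlates with the
   expression of a gene within 500 kb, judged against matched-background
   nulls (`linkPeaksToGenes()`).
2. **DORC analysis** — genes with a high density of CREs (at least 9 by
   default) are *domains of regulatory chromatin*; their per-cell score
   is summed CRE accessibility (`callDorcs()`, `dorcScores()`).
3. **TF activity** — chromVAR-style per-cell motif deviation scores and
   their correlation with TF expression (`computeDeviations()`,
   `deviationExpressionCorrelation()`).
4. **TF–DORC regulation network** — a signed conjunctive score per
   TF × DORC pair (`scoreTfDorc()`, `buildNetwork()`).
5. **GWAS integration** — LD expansion of lead variants, SNP-in-CRE
   prioritization with a matched-background permutation test, and
   partitioning of SNP heritability across weighted gene programs by
   stratified LD-score regression (`expandLD()`, `mapSnpsToGenes()`,
   `permutationEnrichment()`, `fitSldsc()`, `conditionalTauStar()`).

Every stage can be validated end to end on synthetic data with planted
truth (`simulateMultiome()`, `simulateLDPanel()`, `simulateSumstats()`),
and `runPipeline()` chains all stages with persisted, re-runnable
intermediate files.

# CRE discovery

Both modalities are depth-normalized to 10,000 counts per cell and
`log1p`-transformed — a deliberately simple, reproducible normalization
with no TF-IDF and no cell smoothing by default. (An upstream k-NN
pseudo-cell aggregation is a common alternative; we keep correlation at
single-cell resolution so the null model stays interpretable.)

For each (peak, gene) pair with peak midpoint within 500 kb of the
gene's strand-aware TSS (strictly less than; intervals are 0-based
half-open, TSS is the interval start on `+` genes and the last base on
`-` genes), we compute the Pearson correlation `r_obs` across cells.
Raw correlations are confounded by technical and compositional
structure, so significance is assessed against a *matched background*:
the `n_bg = 200` peaks nearest to the tested peak in the plane of
standardized GC fraction and standardized log1p mean accessibility
(ties broken by ascending peak index, so matching is deterministic and
needs no seed). The background z score

$$z = \frac{r_{obs} - \mathrm{mean}(r_{bg})}{\mathrm{sd}(r_{bg})}$$

is converted to a two-sided normal p-value and BH-corrected globally
over all tested pairs (one genome-wide CRE map, not per-gene lists).
Pairs with FDR < 0.05 **and positive correlation** are CREs — enhancer
semantics; significant negative links stay in the table flagged
non-CRE. Peaks or genes with zero variance, and pairs with zero
background spread, are skipped with a warning.

# DORCs and the treatment response

A gene with ≥ 9 CREs is a DORC; its per-cell score is the sum of
normalized accessibility over its CREs. `deltaResponseCorrelation()`
contrasts exposed ("oxldl") and unexposed cells: per DORC gene it takes
the difference in mean DORC score and in mean normalized expression,
and correlates the two deltas across genes. A strongly positive R says
chromatin and transcription respond to the stimulus in a coordinated
way.

One caveat the synthetic experiments make explicit: when expression is
mechanistically coupled to accessibility (which is what makes CREs
detectable in the first place), the delta correlation does **not**
vanish under treatment-label permutation — the deltas shrink to the
sampling-noise scale, but their correlation reflects the per-cell
coupling. The permutation-null tests therefore assert that the response
*magnitude* collapses under shuffling, not that R goes to zero.

# Motif deviation scores

For TF $m$ with motif peak set $S$, the expected aggregate count of
cell $i$ under the average accessibility profile is
$e_{im} = (\mathrm{cellsum}_i / \mathrm{total}) \sum_{j \in S}
\mathrm{peaksum}_j$, and the raw deviation is $(o_{im} - e_{im}) /
e_{im}$. Deviations are computed on raw counts (the expectation model
is count-multiplicative). Each of `n_bg = 50` background iterations
replaces every member of $S$ with one peak drawn from its 50
GC/accessibility-matched neighbours; the deviation z standardizes the
raw deviation against this background ensemble. Per-TF mean deviation
and the Pearson correlation with the TF's own expression classify TFs
as activator-like (positive, FDR < 0.05), repressor-like (negative) or
non-significant.

On data with genuine cell-subpopulation structure the deviation z of a
random peak set is over-dispersed relative to N(0,1) — any coherent
peak set picks up real subpopulation signal. The N(0,1) calibration
claim holds under peak-label permutation within matched-feature strata
on unstructured data, and that is what the test suite checks.

# The regulation score

Every TF × DORC pair is scored on two axes: motif over-representation
in the DORC's CREs (observed hit count vs. mean/sd over matched
background peak sets of equal size, one-sided) and Spearman correlation
between TF expression and DORC score across cells. The signed score is

$$\mathrm{reg} = \mathrm{sign}(\rho)\,\min(-\log_{10} p_{enrich},
-\log_{10} p_{corr}),$$

a conjunctive definition: an edge is strong only if the motif is
enriched *and* expression tracks accessibility. The published analyses
this mirrors do not print their exact score formula, so this definition
is declared as this package's; the default strong-edge threshold
|reg| > 1.5 is kept, but score-scale comparability with other
implementations is not claimed. The score is antisymmetric under
negating TF expression and edge counts are monotone in the threshold —
both properties are tested.

# GWAS variant prioritization

Lead variants are expanded by LD: every SNP with r² > 0.8 (strict) to
any lead joins the set, tagged by its max-r² lead; LD is not chained.
SNP positions are 1-based on input (VCF convention) and converted to
0-based for half-open interval containment, so a SNP at a peak's start
coordinate is inside and one at its end coordinate is not. A SNP inside
a CRE is paired with *all* genes linked to that CRE; the summary
reports counts, the median SNP–TSS distance, the fraction of pairs
beyond 10 kb, the fraction where the linked gene is simply the nearest
gene, and — when an eQTL table is supplied — the share of prioritized
SNPs that are known eQTLs and the share of pairs with a concordant
target.

The enrichment test replaces each CRE peak with one draw from its 50
matched non-CRE peaks (pool excludes all CREs to avoid null
contamination; per-peak replacement preserves the set's size and
feature profile), recounts SNP overlaps `n_perm = 1000` times, and uses
the add-one estimator `p = (1 + #{null >= obs}) / (1 + n_perm)`, which
is bounded below by 1/(n_perm+1) and never returns zero.

# Heritability partitioning

**Gene programs.** Differential expression (two-sided Wilcoxon
rank-sum per gene; log2 fold change computed Seurat-style on
back-transformed group means with pseudocount 1) feeds a weighted gene
program $w_g = \min(-\log_{10}\mathrm{FDR}, 10)/10$ for up-regulated
genes — a capped saturation so weights live in [0,1] — or a binary
program (FDR < 0.05 and up). Both modes are first-class.

**SNP annotations.** Each CRE of a program gene carries the gene's
weight; a SNP under several weighted CREs takes the **maximum** weight
(summing would let overlapping CREs of one gene inflate its own
annotation); SNPs under nothing get 0.

**LD scores.** $\ell(j,c) = \sum_k \tilde r^2_{jk} a_c(k)$ over SNPs
within 1 Mb, including $k=j$, with the bias-adjusted
$\tilde r^2 = r^2 - (1-r^2)/(n-2)$ computed from the reference
haplotypes ($n$ = haplotype count). The vectorized routine computes all
in-window sample correlations, so it agrees with a brute-force double
loop to 1e-10 (tested on 500 SNPs).

**Regression.** χ² statistics are regressed on $\{N\,\ell(j,c)\}$ with
a free intercept by weighted least squares: first pass with weights
$1/\max(\ell_{base},1)$, then one refinement multiplying in the
heteroscedasticity factor $1/(2(\hat\chi^2_j)^2)$ from the first-pass
fit (one-step, not fully iterated). Rank-deficient designs (duplicated
annotations) are rejected outright. Standard errors are delete-one
block jackknife over contiguous SNP blocks (default `min(200, M/25)`;
when the LD-block length is known, choosing jackknife blocks at least
that long keeps the SEs honest). Reported per annotation: $\hat\tau_c$,
the heritability share, enrichment (share of h² over share of SNPs —
identically 1 for the all-SNP base annotation), and the standardized
effect size $\tau^*_c = \hat\tau_c\,\mathrm{sd}_j(a_c)\,M/h^2$ with its
jackknife p-value. Conditional analysis (`conditionalTauStar()`) is a
single joint fit — base + background + all listed programs — with each
program's τ* read off the joint coefficients.

The real-data values this framework produced in its source study
(e.g. specific τ* values and the share of heritability in macrophage
CREs) require the original multiome and CAD GWAS; they are not
reproducible from synthetic data and are not asserted anywhere in this
package.

# The synthetic-data generator

`simulateMultiome()` emulates, at desk scale, the data features the
pipeline relies on; defaults are the conditions used throughout the
tests: 2,000 cells, 500 genes, 5,000 peaks on one 100 Mb chromosome,
4 subpopulations, 20 TFs, 2% of peaks carrying planted cis links
(concentrated ~5 per linked gene so DORC calling is exercised),
log-scale link effect 1.0, NB size 2 for RNA, Poisson ATAC with
Gamma(shape 10) per-cell depths around 5,000 counts, and a 50/50
treatment split.

Generative sketch: peak log-accessibility = global baseline (sd 1) +
per-subpopulation deviation (sd 0.3) + motif term (TF activity × ±1
sign × 0.5) [+ treatment shift on response-linked peaks]; ATAC counts
are Poisson around depth-scaled softmax accessibilities. Gene log-mean
= baseline + marker boosts + TF-activity coupling (for TF genes) +
`link_effect` × centered normalized accessibility of the gene's linked
peaks; response genes additionally get a heterogeneous fold change
(per-gene scale Uniform(0.2, 1.8) on both the chromatin shift and the
expression effect — a homogeneous response would leave the
delta-response correlation without a between-gene signal axis). One
TF → gene program is planted explicitly: the first TF's motif covers
the most-linked gene's peaks, so that gene's chromatin tracks the TF.

What it does **not** emulate: doublets, ambient RNA, batch effects,
fragment-level ATAC, realistic motif co-occurrence, or distance-decay
of regulatory effects. Passing tests therefore demonstrate the
statistical machinery (calibration of the nulls, recovery of planted
effects at the stated sizes), not performance on real tissue.

Peak GC is Uniform(0.3, 0.7) independent of signal by default, so
background matching is exercised without confounding; `gc_confounded =
TRUE` ties GC to baseline accessibility to stress-test the matching.

**GWAS side.** `simulateLDPanel()` builds binary haplotypes by a
first-order copy process: within a block, each haplotype copies its
previous allele with probability `decay`, else redraws Bernoulli(maf)
(maf ~ Uniform(0.05, 0.5)); blocks are independent, SNPs sit at 1 kb
spacing. `simulateSumstats()` draws standardized per-SNP effects
$\beta_j \sim N(0, \sigma^2_j)$ with $\sigma^2_j = \sum_c \tau_c
a_c(j)$ (negatives clipped with a warning; total above 1 is an error),
genotypes a cohort of N individuals as *fresh draws from the same
copy process* (`simulateGwasCohort()`), sets the environmental variance
so the phenotype has unit variance, and emits marginal regression z
scores, so $E[\chi^2_j] = 1 + N\sum_c \tau_c\,\ell(j,c)$ holds with
panel-computed LD scores. Drawing the cohort by resampling panel
haplotypes instead would promote the panel's sampling-noise r²
(≈ 1/n_hap per pair) into genuine genome-wide LD for the cohort,
inflating every χ² by ≈ N·h²/n_hap and destroying the intercept — with
a 200-individual panel, N = 10,000 and h² = 0.3 the intercept lands
near 10. Keeping the panel as an *independent* reference, as a real
reference panel is, restores the model (null intercepts average 1.0 in
the test suite). The cohort can be reused across phenotype replicates,
but replicate-level inference in the tests regenerates it each time so
replicates stay independent.

# Numerical and design details worth knowing

- All tables are S4Vectors `DataFrame`s; coordinates are `GRanges`
  (1-based closed) internally and 0-based half-open in all flat files;
  TSVs use tab separators, `.` for NA, LF endings, and carry `#`
  provenance headers (package version, seed, content checksum — no
  timestamps, so identical runs produce identical bytes).
- All FDRs are Benjamini–Hochberg. All randomized routines take an
  explicit seed; background *matching* is deterministic.
- Background-degenerate cases are defined, not NaN: zero background
  spread in linking skips the pair with a warning; in motif enrichment
  a flat background yields p = 1 unless the observation exceeds it
  (then the add-one floor); constant annotations make τ* NA; negative
  h² suppresses τ* with a warning.
- The jackknife first pass of `fitSldsc()` floors fitted χ² at 0.05
  when forming heteroscedasticity weights; `computeLdScores()` chunks
  500 SNPs at a time so memory stays flat.
- Problem sizes in the test suite: CRE recovery and the delta analysis
  run at the default 2,000 × 500 × 5,000 scale over 10 seeds; the
  null-calibration runs use 1,000 cells × 300 genes × 2,500 peaks; the
  S-LDSC experiments use M = 5,000 SNPs (250 × 20 blocks, decay 0.9),
  N = 10,000, 50 recovery and 50 null replicates with 125 jackknife
  blocks (aligned to the 20-SNP LD blocks); the permutation test uses
  2,000 peaks, 200 SNPs and 1,000 permutations. Mechanism-isolating
  unit tests drop to one subpopulation to remove confounding by
  design.

# Known limitations

- The background-z null for peak–gene linking is conservative for
  genes with many subpopulation-structured CREs (their expression
  inherits a broad subpopulation profile, widening the background
  spread); recovery of very-high-CRE-density genes needs more cells.
- The regulation score's scale depends on `n_bg` through the
  resolution of the empirical enrichment p-values; thresholds are
  comparable within a run, not across settings.
- S-LDSC at desk scale (M in the thousands) has limited
  intercept/τ_base separation compared to genome-wide data; jackknife
  SEs are honest about this, but point estimates of total h² are
  noticeably noisier than the per-annotation τ and enrichment.
- `differentialStats()` is a per-gene Wilcoxon test: fine for the
  program weighting it feeds, not a replacement for count-model DE
  frameworks when absolute effect sizes matter.

# A worked example

```{r example, eval = FALSE}
library(macroCRE)
sim <- simulateMultiome(simMultiomeConfig(seed = 1))
links <- linkPeaksToGenes(sim$multiome, n_bg = 200)
dorcs <- callDorcs(links, min_cres = 9)
dev <- computeDeviations(sim$multiome, sim$truth$motif_hits, seed = 1)
head(deviationExpressionCorrelation(dev,
    normalizeCounts(rnaCounts(sim$multiome))))

## or the whole pipeline:
cfg <- pipelineConfig("pipeline_out", seed = 1)
runPipeline(cfg)
```
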