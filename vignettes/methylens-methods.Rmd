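---
title: "Methods: linking DNA methylation to chromatin accessibility and expression"
author: "methylens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking DNA methylation to chromatin accessibility and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylens)
```

## The analysis in one paragraph

`methylens` implements an integrative two-condition epigenomics analysis
modelled on the differentiation of eye-lens epithelial cells (group 1, the
reference state) into fiber cells (group 2). Whole-genome bisulfite
sequencing gives per-CpG methylated/total read counts for biological
replicates of both states; the package calls differentially methylated
regions (DMRs) with a smoothed beta-binomial site test, assigns them to
genomic features with a strand-aware priority scheme, and asks three
questions: do DMRs concentrate in particular genomic features beyond what
random placement predicts; do per-gene methylation changes track expression
changes (Pearson correlation and a 2x2 quadrant chi-square); and do
methylation changes track chromatin accessibility changes from ATAC peaks,
individually and in a three-way site classification. A final module scans
DMR sequences with JASPAR position weight matrices, using exact
score-distribution p-values, and tests motif enrichment against shuffled
backgrounds with an expression-aware filter on the transcription factors.
All fold changes and methylation differences are oriented group2/group1
(fiber minus epithelial), so a positive `diff_methyl` means hypermethylated
in the differentiated state.

## The DMR caller

The caller follows the DSS family of methods: a beta-binomial model across
biological replicates, spatial smoothing of methylation levels, site-level
tests, and rule-based segmentation. The published internals of DSS's
Bayesian shrinkage are not reproduced here; this is a documented
simplification with the same region-calling parameterisation, and
equivalence with DSS is explicitly not claimed.

**Smoothing.** For site $i$ and group $g$, the smoothed methylation level is
the pooled proportion over every CpG within `smoothing_span / 2` bp
(default span 200, i.e. a $\pm 100$ bp inclusive window):

$$\hat\mu_{ig} = \frac{\sum_{j \in W_i} \sum_r m_{jgr}}{\sum_{j \in W_i} \sum_r N_{jgr}}$$

A span of 0 degenerates to the per-site pooled proportion. Sites whose
window has zero coverage in either group are dropped with a message.

**Dispersion.** The beta-binomial overdispersion $\varphi$ is parameterised
so that a replicate's proportion has variance
$\mu(1-\mu)\,(1 + (N-1)\varphi)/N$; $\varphi = 0$ is exactly binomial
(the generator uses $\alpha = \mu(1-\varphi)/\varphi$,
$\beta = (1-\mu)(1-\varphi)/\varphi$). Per site, a method-of-moments
estimate is formed in each group with at least two replicates from the
across-replicate variance of proportions; the group estimates are averaged
before clamping to $[0, 0.99]$ — averaging first roughly halves the skew of
the chi-square-like sampling distribution of a single-group variance, so
the genome-wide median used as the shrinkage target is approximately
centred on the true $\varphi$. Each site's estimate is then shrunk,
$\varphi^* = (k\bar\varphi + m\hat\varphi)/(k+m)$, with $k$ prior
pseudo-observations (default 10), $m$ the number of replicates that
informed the site, and $\bar\varphi$ the genome-wide median. Sites without
an estimate (or single-replicate designs, with a warning) receive
$\bar\varphi$.

**Site test.** The Wald statistic divides $\hat\mu_2 - \hat\mu_1$ by the
standard error implied by treating every replicate-by-window-CpG read
total $N_j$ that entered the pooled estimate as one beta-binomial
observation:

$$\mathrm{Var}_g \;=\; \frac{\hat\mu(1-\hat\mu)\left[(1-\varphi^*)W + \varphi^* S\right]}{W^2},
\qquad W = \sum_j N_j,\; S = \sum_j N_j^2 .$$

This is the point where a design decision was genuinely open: the variance
could be computed from the focal site's reads only. We use the window reads
because they are exactly the observations the smoothed estimator pools —
with site-only totals the statistic ignores most of the information the
estimator uses, and at three replicates per group and $\varphi = 0.1$ the
attainable $|z|$ is bounded near 3 regardless of coverage, which makes a
$p < 10^{-5}$ site threshold unusable. Two-sided normal p-values follow;
degenerate sites (both groups at 0 or 1 with $\varphi^* = 0$) get $p = 1$
when the means agree and are otherwise flagged unstable and excluded.

**Segmentation.** With the default parameters (`p_threshold = 1e-5`,
`delta = 0` so significance is the p-value alone, `minlen = 50`,
`minCG = 3`, `dis_merge = 100`, `pct_sig = 0.5`), significant CpGs are
chained whenever the gap to the previous significant CpG is under
`dis_merge` bp (strict `<`); chaining across a small gap absorbs any
non-significant CpGs in between. A region's span is `last - first + 1`
over its CpG positions — so three CpGs at 0/25/49 span exactly 50 and pass
`minlen` — and `pct_sig` is evaluated after merging, over all CpGs in the
region including absorbed ones. `diff_methyl` is the unweighted mean of
$\hat\mu_2 - \hat\mu_1$ over the region's CpGs, and its sign defines the
hyper/hypo direction. These tie-breaks are pinned by oracle tests against
an independent brute-force segmenter.

## Annotation and the random-placement null

Features are ranked promoter > 5'UTR > first exon > first intron > other
exon > other intron > 3'UTR > CpG island > CGI shore > repeat > intergenic;
an interval takes the highest-priority category it overlaps by at least
1 bp. The promoter is the 2 kb upstream of the TSS, strand-aware, and can
be subdivided into a proximal (nearest 1 kb) and distal zone. The priority
order is this package's decision — promoter first because promoter DMRs are
the analysis' distinct headline class.

The distribution null redraws the observed DMR set `n_draws` times with
lengths resampled from the observed length multiset and uniform placement
over the genome (no gap masking), annotates each draw identically, and
compares observed to mean expected counts with a Pearson chi-square
(categories with expected counts below 1 pooled). With the default
`n_draws = 50` the Monte-Carlo error in the expected counts inflates the
statistic by about $1 + 1/n_{\mathrm{draws}} = 2\%$, and the self-null
rejection rate at $\alpha = 0.05$ measures ~0.055 in the acceptance suite.
All chi-squares in the package are Pearson without continuity correction:
with Yates' correction the published promoter-scope quadrant table
(208/58/15/30) gives $p \approx 1.8\times10^{-9}$, which contradicts the
printed bound $p < 10^{-9}$, while the uncorrected statistic reproduces
both printed bounds.

## Expression, chromatin and triple integration

Genes are classed fiber-preferred (`log2fc > 0.4`, `q < 0.05`),
epithelial-preferred (`log2fc < -0.4`, `q < 0.05`) or not differential;
inequalities are strict, so boundary values are not differential. Per gene,
the methylation change is the unweighted mean `diff_methyl` of DMRs linked
to its promoter or gene body (promoter-only as a second scope; a DMR
touching both features of one gene counts as promoter). A weighted mean
(by CpG count or length) is available but not default, since the analysis
this mirrors specifies a plain average. Genes whose average change is
exactly zero are excluded from the direction dichotomy and counted
separately. Correlation is Pearson with the usual $t$-transform p-value on
$n-2$ degrees of freedom.

ATAC peaks are opening (`log2fc > 0`, `q < 0.05`), closing (`log2fc < 0`,
`q < 0.05`) or stable — `q = 0.05` exactly lands in stable to keep the
partition total. Each DMR is matched to its best single overlapping peak
(largest overlap, then smaller q, then leftmost; overlap at least 1 bp on
half-open intervals, so abutting features do not overlap). Triple sites are
(DMR, gene) pairs whose DMR overlaps a differential peak and whose gene is
differentially expressed; a DMR inside two genes' bodies contributes two
sites, and both pair-level and gene-level (rollup) counts are emitted. A
site is concordant when it matches the canonical inverse-methylation
pattern: hypomethylated + opening at a fiber-preferred gene, or
hypermethylated + closing at an epithelial-preferred gene.

## Motif scanning and enrichment

Position frequency matrices are converted to bit-scaled log-odds with a
0.25 pseudocount per cell against a zero-order background estimated from
the scanned sequences (overridable). Scores are discretised to 0.01-bit
bins and the exact distribution of a background word's score is obtained by
dynamic-programming convolution over columns; scanning uses the same
discretised matrix, so the reported p-value is exactly the tail probability
of the observed (discretised) score. Hits are offsets on either strand with
$p < 10^{-4}$ (a threshold of 1 is the degenerate report-everything
setting). Enrichment is a one-sided Fisher's exact test on the number of
sequences with at least one hit, primary versus shuffled control, adjusted
with Benjamini-Hochberg across motifs. This fixes concretely what "default
settings" of AME-style enrichment leave open; AME's own scoring differs,
and rank order is the comparable quantity. The default control is a
mononucleotide shuffle; an Euler-path dinucleotide shuffle that preserves
all 16 adjacency counts is available. Enriched motifs are finally filtered
by transcription-factor expression: the TF name is mapped to a gene
case-insensitively (heterodimer names split on `::`, kept when any part
passes), motifs whose TF falls under 1 summed FPKM are dropped, and
unmapped TFs are retained but flagged.

## The synthetic-data generator

The generator emulates the data structure of the study, not its biology in
detail. Defaults encode the validation conditions used throughout: planted
effects of $\pm 0.4$ methylation proportion over 200 bp spans, 30x mean
Poisson coverage (floored at one read), three replicates per group, and
$\varphi = 0.1$ across replicates. Choices the study conditions left open
were fixed once:

* **CpG density 0.04/bp.** Bases are drawn i.i.d. with
  $P(C) = P(G) = \sqrt{0.04}$, which makes the expected CpG density exactly
  the configured rate; CpG islands are re-drawn at four times the rate.
  This is denser than a vertebrate genome-wide average and comparable to
  gene-regulatory neighbourhoods, which is where the analysis operates.
* **Base methylation 0.5.** Mid-range, so symmetric $\pm 0.4$ effects stay
  inside the clamp $[0.02, 0.98]$ without asymmetry.
* **Planted regions anchor on CpG clusters.** A planted region's start
  snaps to a CpG position and the window is chosen to contain at least the
  expected CpG count (minimum 5): a "differentially methylated region" is
  defined by the CpGs it contains, and arbitrary bp boundaries would leave
  regions whose CpGs clump at one edge, making planted truth ill-defined
  for power evaluation. Signs are balanced 50/50.
* **Couplings by closed form.** With balanced signs the predictor
  `avg_diff_methyl` has standard deviation equal to the effect size, so for
  target correlation $r$ the noise is
  $\sigma = |s|\,e\,\sqrt{1/r^2 - 1}$ for slope $s$ and effect $e$
  (`coupling_noise_for_r()`). Defaults target $r = -0.4$ for expression and
  $r = -0.86$ for accessibility, the magnitudes the integrative analysis is
  designed to detect.
* **q-values are assigned, not estimated.** Differential-expression and
  peak-calling fits are outside scope; genes/peaks carrying true signal get
  $q < 0.05$ with probability 0.95, others with probability 0.05.

What the generator does **not** emulate: read-level bisulfite conversion
error, non-CpG (CHG/CHH) methylation (context classification is tested on
literal sequences instead), covariation of coverage with GC content,
correlated replicate effects along the genome, and realistic gene-length or
expression distributions. Passing tests therefore demonstrate the
correctness and calibration of the machinery under its stated model, not
performance on real lens data.

## Problem sizes and numerical choices

The test and acceptance suites run end-to-end on one CPU in minutes by
scaling the simulations: coupling recovery uses 1000 planted regions on a
7 Mb genome; DMR power uses 500 planted regions on 9 Mb (about 360k CpGs,
six replicates); the null-rate check uses about 10^5 CpGs; the
random-placement calibration uses 200 repetitions of 60 intervals with 50
draws each; motif-enrichment recovery uses 50 sequences of 200 bp per arm.
Score discretisation is 0.01 bits; dispersion clamps to $[0, 0.99]$;
methylation means clamp planted shifts to $[0.02, 0.98]$; a cytosine counts
as "methylated" for context proportions at one pooled methylated read
(configurable — the underlying study does not state its threshold).

## Known limitations

* The caller is a documented simplification of DSS, not a reimplementation;
  on real data the two will differ in region boundaries and borderline
  calls. At the validation conditions its calls are systematically shorter
  than the planted 200 bp truth (bounded by the significant-CpG run), which
  is why recovery is scored at 50% reciprocal overlap.
* The random null does not mask assembly gaps; on a real genome a gap-aware
  placement would be needed.
* Nearest-gene assignment is operationalised as promoter/gene-body overlap;
  a DMR near but not touching a gene links to nothing.
* Motif enrichment counts sequences with hits; it ignores hit multiplicity
  within a sequence, as the underlying Fisher design requires.
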