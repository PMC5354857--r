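---
title: "Methods and design of the lncnet pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the lncnet pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

`lncnet` implements the downstream computational arc of a paired
lncRNA/mRNA tumor-versus-normal expression study — differential
expression, positional lncRNA classification, co-expression networks,
pathway enrichment, and qPCR validation — together with a synthetic-data
generator that plants known truth into every input. This vignette
explains the statistical procedures, the tunable parameters, the
numerical conventions, and what the synthetic test bed does and does not
establish about real data.

## The study design being emulated

The reference design is a gonadotrophin-adenoma cohort: 11 tumor
specimens against 5 autopsy-derived normal pituitary glands, profiled at
the gene level as FPKM-like non-negative abundances for both coding
genes and lncRNAs. The pipeline starts after quantification; read
processing, alignment and transcript assembly are out of scope.

## Differential expression

Fold change is computed on group means with a pseudocount:

$$\mathrm{FC}_g = \frac{\bar{x}^{tumor}_g + c}{\bar{x}^{normal}_g + c},
  \qquad c = 0.25 .$$

The pseudocount keeps fold changes finite for genes undetected in one
group; without it, genes switched off in one condition (the most
dramatic finding of such studies, with |log2FC| near 14) would be
uncomputable. The same $c$ is used inside the variance-stabilising
transform $\log_2(x + c)$ on which the per-gene two-sided Welch t-test
runs. Welch's unequal-variance form is the right default for an 11-vs-5
design; the unit-scale choice $c = 0.25$ is conventional for FPKM.

Multiple testing uses the Benjamini–Hochberg step-up,
$q_{(i)} = \min_{j \ge i} \; m\, p_{(j)} / j$, implemented explicitly
(and cross-checked against `p.adjust` in the tests) so that the
oracle-equivalence tests exercise a genuine dual route. FDR is computed
within each biotype separately, because lncRNAs and mRNAs are reported
as separate populations throughout this literature; `fdr_by = "pooled"`
switches to a joint correction.

A gene is significant iff `FC > 2` **or** `FC < 0.5`, **and**
`p < 0.05`, **and** `FDR < 0.1` — all strict inequalities, following
the printed form of the rule ("> 2.0 or < 0.5"). A gene at exactly
FC = 2 is therefore not called. A secondary cut (default FC > 10 or
< 1/10) counts extreme responders among the significant genes.

Heat-map ordering uses average-linkage agglomeration on the correlation
distance $1 - r$. `stats::hclust` leaves tie resolution unspecified, so
the package implements the agglomeration itself with a fixed rule —
ties in merge distance are broken by the lexicographically smallest
member id, and the cluster containing the smaller id is placed on the
left — making leaf orders reproducible across platforms. Constant
(zero-variance) genes have no defined correlation and are assigned the
maximal distance 2 with a warning. Tests compare the merge heights with
a brute-force agglomerator that recomputes mean pairwise distances at
every step.

## Positional classification of lncRNAs

The six-category taxonomy (exonic sense, intronic sense, exonic
antisense, intronic antisense, bidirectional, intergenic) is common in
lncRNA catalogues but rarely given an operational definition. The
package fixes one, chosen to be deterministic and testable:

1. `exonic_sense` — any lncRNA exon overlaps a same-strand coding exon
   by ≥ 1 bp;
2. `intronic_sense` — the lncRNA span lies inside a same-strand coding
   gene span with no exonic overlap;
3. `exonic_antisense`, 4. `intronic_antisense` — the opposite-strand
   analogues;
5. `bidirectional` — no overlap with any coding span, and the lncRNA
   transcription start lies within `promoter_window` (default 1000 bp,
   the common divergent-promoter convention; the distance cut-off used
   by any given published catalogue is generally unknowable) of an
   opposite-strand coding transcription start;
6. `intergenic` — everything else.

Because the rules are ordered, every lncRNA receives exactly one label
regardless of how many coding genes it touches or in what order they
are scanned; strand-flipping the whole annotation leaves labels
unchanged. Classification is at gene level (transcripts collapsed to
exon unions). Internally coordinates are 0-based half-open; GTF I/O
(via `rtracklayer`) converts to and from the format's 1-based inclusive
convention, and a round-trip test audits the conversion.

## Co-expression networks

Edges connect lncRNAs to mRNAs by Pearson correlation across the tumor
cohort (the cohort in which co-regulation is biologically at issue;
`cohort = "all"` is available). Correlations are computed on
$\log_2(x + c)$ by default: on the raw FPKM scale a product-moment
correlation is dominated by the most abundant samples, and log-scale
correlation is the norm in co-expression analysis. `log2_transform =
FALSE` restores the raw scale.

Two regimes mirror standard practice: the general network keeps
`|PCC| >= 0.90` with no p cut, and the pathway-seeded sub-network keeps
`|PCC| >= 0.80 & p < 0.001`, with p from the t transform
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df. The magnitude is
thresholded and the sign kept as an edge attribute, so strongly
anti-correlated pairs are linked too. Boundary convention: `>=` for the
correlation cut-off (the inclusive form appears in how such thresholds
are usually quoted), strict `<` for p. Edge p-values are deliberately
not FDR-adjusted — the sub-network rule is a raw `p < 0.001` filter —
though `bh_fdr()` can be applied to the edge list by the user. Constant
genes are dropped before correlation with a warning. Nodes are exactly
the endpoints of retained edges; degree is the neighbour count, ranked
with lexicographic tie-breaking.

## Pathway enrichment and the pathway-act network

Enrichment is the one-sided Fisher exact test: with a universe of $N$
detected genes, $n$ of them differentially expressed, a set of size $K$
and overlap $k$, the p-value is the hypergeometric upper tail
$P(X \ge k)$. The universe defaults to the genes detected in the
matrix, not the genome — the standard choice that avoids inflating
enrichment with never-observed genes. Sets are kept when
$-\log_{10}(p) > 1.3$ (p below $10^{-1.3} \approx 0.0501$, strict); no
multiple-testing correction is applied to pathway p-values, matching
the conventional raw `-log(P)` filter, with an optional BH mode.

Commercial pathway tools attach a proprietary activation prediction to
each pathway. The package substitutes an openly specified
sign-consistency statistic: over the set's DE members that carry an
expected direction annotation,
$z = (n_\text{consistent} - n_\text{inconsistent})/\sqrt{n}$, with
$z \ge 2$ labelled activated, $z \le -2$ suppressed, otherwise
unpredicted. It is a stand-in labelled as such in output metadata, not
a reimplementation of any vendor algorithm.

The pathway-act network joins, among the `top_k` most significant sets
(default 20, covering the usual top-twenty chart; the top-15 variant is
one argument away), every pair sharing **strictly more than**
`min_shared = 5` DE genes — a pair sharing exactly 5 gets no edge.

## qPCR quantification

Relative expression follows $2^{-\Delta\Delta C_t}$: replicate wells
(three by default) are averaged arithmetically on the Ct scale,
$\Delta C_t = \bar{C_t}^{target} - \bar{C_t}^{reference}$ per sample,
and the calibrator is the mean normal-group $\Delta C_t$ — equivalent
to calibrating on the control group's geometric mean, so the normal
group's mean relative expression is 1 by construction. Protocols that
calibrate on a single control sample are supported via
`calibrator = "<sample_id>"`. Because $\Delta\Delta C_t$ is a double
difference, adding any constant to every Ct cancels exactly (shift
invariance), and with zero noise the estimated fold change equals the
planted one exactly. Group comparison is a Welch t-test by default
(11-vs-5 group sizes make pooled variance a poor default), with the
pooled-variance Student variant available.

## The synthetic-data generator

The generator exists to make every downstream claim testable against
planted truth.

* **Baseline**: each gene's log2 abundance is Normal around a per-gene
  mean drawn from Uniform[2, 8], i.e. a log-normal abundance model. The
  pipeline consumes post-quantification FPKM-like values, so a
  count-level negative-binomial model would add realism the statistics
  downstream never see; log-normal is our choice, not a claim about the
  reference study.
* **Planted DE**: selected genes get a tumor-group log2 shift of
  `planted_log2fc` (default 4, noise SD 0.3) — the group-mean
  difference is exact at zero noise.
* **Planted correlations**: each correlation module is a star; the hub
  gene carries a latent factor standardized over the tumor samples, and
  each partner carries $\lambda z + \sqrt{1-\lambda^2}\,e$ with $e$
  residualized against $z$ in-sample, so the realized tumor-cohort PCC
  equals the target exactly before noise. The factor amplitude is 2.5
  log2 units — a ~5.7-fold co-regulated swing, large but of the kind
  tumor co-expression modules show — chosen once so that edges planted
  at PCC 0.95 survive measurement noise (SD 0.3) and the 0.90 threshold
  with high probability at n = 11.
* **Annotation**: each lncRNA occupies its own 100-kb neighbourhood
  with a partner coding gene constructed so its true category is
  unambiguous; category counts follow the requested proportions by
  largest-remainder apportionment (exact for integer cases). The
  default proportions follow the mix reported for dysregulated lncRNAs
  in pituitary-adenoma profiling (≈ 13/8/20/15/1/42 percent).
* **Pathways**: DE-gene content per set and pairwise shared-DE counts
  are exact by construction; all other members are set-exclusive.
* **qPCR**: reference gene at a fixed baseline Ct, targets shifted by
  $-\log_2(\text{fold change})$ in tumors, per-well Normal noise.

Every generator derives its RNG stream from the mandatory config seed;
identical configs give byte-identical outputs, and there is no hidden
global state.

**What passing tests show — and what they do not.** The synthetic bed
has independent Gaussian noise, no batch effects, no
library-size artefacts, no outlier samples, and correlation structure
confined to the planted modules. Recovery results (DE sensitivity ≥
0.9 at |log2FC| = 4, planted-edge sensitivity ≥ 0.9 at PCC 0.95) are
therefore statements about the pipeline's correctness under its own
model, not about power on real tumor cohorts, where dropout,
heteroscedasticity and global co-expression will lower both.

## Numerical conventions and degenerate inputs

* Zero variance in both groups: Welch p is 1 for equal means, the
  smallest positive double for unequal means (never NaN).
* `FDR = 0` maps to a capped 320 on volcano y-axes.
* `|r| = 1` maps to p = 0 in the correlation t transform.
* Constant vectors: errors in the scalar correlation API; dropped with
  a warning (and counted) in network construction; maximal distance in
  clustering.
* Strictness: significance thresholds, the `-log10(p) > 1.3` filter
  and the `> 5` shared-gene rule are strict; the correlation cut-off
  `>= 0.90` is inclusive.
* Chromosome names are normalized to the `chr` prefix.

## Problem sizes

Test and demo simulations run at 100–500 genes per biotype — small
enough for exhaustive oracles (brute-force hypergeometric tails,
all-pairs network reconstruction, step-by-step agglomeration) while
every statistic involved is scale-free. The recovery studies use 50
simulation replicates for DE, 10 for planted edges and 5 for the null
edge rate; these sizes give Monte-Carlo error well inside the margins
being asserted.

## Known limitations

* The DE test is a Welch t-test on log2 values, not a nested-model
  test on assembled transcripts; with 5 controls its power profile
  differs from count-based methods.
* The activation score is a transparent stand-in; it will not
  reproduce proprietary activation calls.
* Classification is gene-level; isoform-resolved positional classes
  are out of scope.
* GMT descriptions are not preserved on read (the reader in use
  discards them); set ids are the stable key.
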