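---
title: "Methods: linking TF binding to chromatin state, super-enhancers, 3D contacts and knockdown response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking TF binding to chromatin state, super-enhancers, 3D contacts and knockdown response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selink)
```

# Scope and model

`selink` implements the integrative desk analysis used to argue that a
transcription factor acts as an activator at super-enhancers (SEs): it takes
peak calls, histone-mark peak sets, coverage tracks, SE/TE catalogues,
promoter-capture Hi-C (PCHi-C) interaction calls and a knockdown
differential-expression (DE) table, and produces compositions, density
contrasts, co-binding statistics with a resampling null, interaction classes
and DE linkages. Upstream read processing (alignment, peak calling,
interaction calling, the DE test itself) is out of scope: the package consumes
their standard outputs.

All coordinates are 0-based half-open throughout (BED convention), including
the gene table, so interval length is `end - start` everywhere and no stage
introduces off-by-one drift.

# Stage-by-stage procedure

## Chromatin state of TF peaks

A peak is called `active_k4me3` when it overlaps an H3K4me3 peak only,
`bivalent` when it overlaps both H3K4me3 and H3K27me3, `repressive_k27me3`
with H3K27me3 only, and `unmarked` otherwise. The rule is pure overlap logic
(no hidden-Markov segmentation) with a >= 1 bp default overlap, exposed as
`min_overlap_bp`. Peaks overlapping neither mark are retained as a fourth
`unmarked` group rather than silently dropped, so peak counts are conserved;
`drop_unmarked = TRUE` reproduces a three-group report.

## Genomic compartments and target genes

Promoters are the 6 kb windows (+/- 3 kb) around each TSS. Compartment
annotation is mutually exclusive with precedence promoter > gene body >
intergenic; a peak overlapping both a promoter window and a gene span counts
once as promoter. The gene body is the span between min(tss, tes) and
max(tss, tes), which handles minus-strand genes whose TSS exceeds their TES.
A gene is a target of a peak when its promoter window overlaps the peak;
peaks may target several genes and vice versa. The `cobind` scheme reports
the same precedence as promoter / intergenic / other, matching the three-way
split used for co-binding site distributions.

## Signal density and metaprofiles

Region density is reads per million per base:
`(signal in region / total_signal * 1e6) / length`, where `total_signal` is
the integral of the coverage track (a library-size proxy). Metaprofiles
sample fixed-width bins around peak midpoints — the midpoint
`floor((start + end) / 2)` is used as the anchor because BED3 input carries no
summit — normalised the same way (per million per bp; the choice is recorded
in the profile object's `units`). Windows truncated at chromosome edges
contribute only their in-bounds bins, keeping per-bin means well defined.
Defaults are a 2 kb radius with 50 bp bins; both are parameters. SE vs TE
density contrasts use the two-sided Wilcoxon rank-sum test, the
distribution-free analogue of a box-plot comparison, and report the median
fold.

## Enhancer taxonomy and SE calling

Candidate regions are classified with the following precedence: overlap with
a supplied SE catalogue gives `super` outright (a published SE list overrides
local mark logic); otherwise H3K27ac marks `active`, H3K27me3 with H3K4me1
marks `poised`, H3K4me1 alone marks `intermediate`, and anything else is
`unclassified`. The mark-to-class mapping for the non-SE classes follows the
standard enhancer-chromatin convention; the "intermediate" definition
(H3K4me1 only) is a documented design choice, since published taxonomies vary
on this point. Each SE is mapped to the gene whose TSS is nearest to the SE
boundary (point-to-interval distance, 0 inside the SE; ties broken toward the
lexicographically smaller gene_id and flagged), unassigned beyond
`max_distance` (default 100 kb).

For users without a published SE catalogue, `stitch_and_rank()` provides the
conventional stitch-and-rank caller: peaks within 12.5 kb are merged, stitched
regions are ranked by total track signal, and the SE/TE cutoff is the tangent
point of a slope-1 line on the axis-scaled ranked curve. When every region
has equal signal, the geometry degenerates; the result is flagged and no SEs
are called. It is never invoked when an SE list is supplied.

## Co-binding and the resampling null

Co-binding is counted at the interval level: a peak counts once no matter how
many partner peaks it touches, matching percentage-of-peaks reporting. A
base-pair mode is available as a flag on `overlap_ci()`. Conditional
fractions stratify one factor's peaks (for example by chromatin state) and
report the per-stratum overlapped fraction; the size-weighted mean equals the
pooled fraction by construction.

The uncertainty attached to an overlap count is empirical: each draw
re-places the query intervals uniformly at random on their source chromosomes
(lengths preserved; no mappability or blacklist exclusion by default, since
an exclusion set is not always available — one can be passed as a shuffle
constraint upstream), and the 95% interval is taken from the 2.5th and 97.5th
percentiles of the draws as order statistics, so the bounds are counts
actually seen under the null. The enrichment p-value uses the add-one rule
`(1 + #{draws >= observed}) / (n_draws + 1)` and can never be 0. The default
is 100 draws, the conventional quick setting; the package's own tests use
1000 draws because percentile endpoints from 100 draws are noisy — this
divergence is deliberate and only affects test stability, not the method.

## PCHi-C interaction classes

Interactions arrive as bait (promoter fragment, with its gene ids) plus
other-end anchors with a pass-through upstream score. Classification looks at
the other end only, with precedence promoter > enhancer: a promoter overlap
gives `promoter_promoter` regardless of enhancer overlap (the bait design is
promoter-centric), an overlap with a classified enhancer gives
`promoter_enhancer` carrying the enhancer subclass (the highest-precedence
class when several are touched), and everything else is `promoter_other`.
"Mediated by" a TF means a TF peak at either anchor by default; the anchor
rule is a parameter. Second-factor enrichment compares anchor-occupancy
fractions between the mediated subset and the full universe with a
two-proportion test. Inter-chromosomal pairs are flagged and their anchor
distance is reported as unbounded.

## Differential expression rule

Fold changes are knockdown / control on the linear scale. A gene is `up` when
`fold_change > 1.3` and `p < 0.05`, `down` when `fold_change < 1/1.3` and
`p < 0.05`, otherwise `ns` — both inequalities strict, so a gene exactly at
1.3-fold is not significant. The reciprocal threshold for `down` is the
standard symmetric reading of a single fold cutoff. No multiple-testing
correction is applied by default, matching the raw-p rule; a BH flag exists.
Gene-set enrichment between peak-derived sets and DE sets uses the one-sided
hypergeometric upper tail.

# The synthetic-study generator

`simulate_study()` writes a complete miniature study — genome, genes, marks,
TF peaks, coverage, SE/TE and enhancer region lists, interactions, DE table —
with every planted parameter recorded in a JSON manifest. Entities are
*placed by construction* to satisfy their labels (an "active" peak is placed
overlapping an H3K4me3 peak and no H3K27me3 peak), rather than sampled and
then labelled, so recovery tests are exact instead of statistical.

The genome is divided into fixed 95 kb territories, each holding one gene and
disjoint zones for SE, TE, enhancer-region and intergenic-peak placement with
>= 3 kb clearance from every promoter window. Planted peaks within a set are
non-overlapping with >= 1 kb spacing so overlap logic is unambiguous, and
histone-mark intervals sit inside their host peak with >= 50 bp margins, which
is why a 20 bp coordinate jitter (the `degrade()` robustness fixture) leaves
every state call unchanged.

Default conditions: 3 chromosomes of 10 Mb; 300 genes; 2000 TF-A peaks with
state composition 0.50/0.20/0.20/0.10 and compartment composition
0.01/0.29/0.70 (promoter / gene body / intergenic); TF-B co-binding at 0.60
pooled, stratified 0.70 (active) and 0.50 (repressive and the remaining
strata); 20 SEs of 10 kb and 60 TEs of 2 kb with a 3-fold SE/TE amplitude
ratio; 100 candidate enhancer regions at 0.10/0.40/0.30/0.20
(super/active/intermediate/poised); 500 interactions at 0.60/0.30/0.10
(P-P / P-E / other) with 0.40 TF-mediated; and a 1000-gene DE table with 120
up and 80 down. These sizes keep a full end-to-end run in the low seconds on
one CPU while leaving every composition statistically meaningful; they are
the package's reference conditions and the ones its acceptance checks use.

Coverage is built as rectangular bumps over region extents — the simplest
shape whose per-base oracle is exact — discretised into 100 bp steps whose
values are Poisson counts at the planted amplitude (`coverage_noise` scales
the Poisson rate: 0 disables noise entirely, larger values reduce relative
noise). With noise disabled the SE/TE median density fold equals the
configured fold exactly; with the default noise it concentrates tightly
around it.

What the generator deliberately does **not** emulate: read-level data and
peak-caller artefacts, mappability gaps and blacklist regions, overlapping or
nested peaks, fragment-level Hi-C structure, genuine biological correlation
between stages (DE status is planted independently of peak placement except
where a test wires them together). Passing recovery tests therefore
demonstrates correctness of the analysis logic under clean inputs, not
robustness to every artefact of real ChIP-seq; the `degrade()` fixture
(coordinate jitter and dropout) covers the first-order imperfections.

# Numerical and reproducibility choices

* Every output table is sorted by (chrom, start, end) and every random step is
  seeded, so reruns are byte-identical; `run_pipeline()` derives one namespaced
  seed per stage from the base seed, so adding a stage does not perturb
  another stage's draws.
* Percentile CI endpoints use type-1 (order statistic) quantiles, keeping the
  bounds on the observed count scale.
* The degenerate cases are explicit: empty peak sets raise errors where a mean
  or fraction would be undefined; empty strata report `NA`, never 0; a
  zero-signal region has density 0; an all-equal ranked curve yields zero SEs
  with a flag; a second factor absent everywhere flags the enrichment ratio as
  undefined.
* `degrade()` drops an exact count `round(n * dropout)` of peaks rather than a
  Bernoulli draw, so the manifest can record the retained set precisely.
* The interaction table distinguishes intra- from inter-chromosomal pairs via
  a flag but reports both under one `promoter_promoter` class; no operational
  definition for splitting them further is imposed.

# Known limitations

* The overlap null model is uniform placement per chromosome; GC, mappability
  and accessibility biases of real data are not modelled.
* `classify_enhancers()` trusts the supplied SE catalogue outright; a stale
  catalogue propagates into interaction subclasses.
* The DE stage starts from a supplied fold-change/p table; it neither
  recomputes the test nor corrects its p-values by default.
* Scores from upstream interaction callers are passed through, never
  re-scored.
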