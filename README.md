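# selink

Integrative analysis of transcription-factor binding at super-enhancers, in R.

`selink` is for regulatory genomicists who have the standard desk outputs of
an activator-TF study — ChIP-seq peak calls for the factor and histone marks,
coverage tracks, a super-enhancer (SE) catalogue, promoter-capture Hi-C
(PCHi-C) interaction calls, and a knockdown differential-expression table —
and want the downstream integration reproducibly scripted:

* **Chromatin state of TF peaks** from histone-mark overlap:
  active (H3K4me3 only), bivalent (H3K4me3 + H3K27me3), repressive
  (H3K27me3 only), unmarked.
* **Genomic compartments** (promoter ±3 kb / gene body / intergenic, mutually
  exclusive with promoter precedence) and promoter-window target genes.
* **Signal density**: peak-centred metaprofiles and per-region density in
  reads per million per base, with a Wilcoxon rank-sum SE-vs-TE contrast of
  median fold, plus an optional ROSE-style stitch-and-rank SE caller.
* **Co-binding statistics** between two factors, stratified by chromatin
  state, with an empirical null: the query set is re-placed uniformly at
  random `n` times and a 95% percentile confidence interval is read off the
  draws (`overlap_ci`), with an add-one empirical p-value.
* **PCHi-C interaction classes** (promoter–promoter / promoter–enhancer with
  enhancer subclass / other), TF occupancy at anchors, and second-factor
  enrichment in TF-mediated interactions.
* **DE linkage**: the fold-change rule `up` iff FC > 1.3 and P < 0.05,
  `down` iff FC < 1/1.3 and P < 0.05 (strict inequalities, linear scale),
  gene-set DE summaries, and hypergeometric set overlap.
* A **synthetic-study generator** (`simulate_study`) that writes a complete
  miniature study with every planted composition recorded in a manifest, so
  the whole pipeline is testable end to end without any external download.

All coordinates are BED-native 0-based half-open. Interval work is built on
GenomicRanges/IRanges; file formats are plain BED, bedGraph, TSV and JSON.

## Worked example

```r
library(selink)

# a complete synthetic study with planted ground truth
man <- simulate_study(sim_config(seed = 1), "bundle")

# run every stage
report <- run_pipeline(bundle_run_config("bundle", "run", seed = 1))
print(report)
#> pipeline run report (selink 0.9.0 )
#>   classify      ok
#>   annotate      ok
#>   profile       ok
#>   enhancers     ok
#>   cobind        ok
#>   interactions  ok
#>   de            ok

s <- report$stages
s$classify$fractions      # 0.5 0.2 0.2 0.1  (active/bivalent/repressive/unmarked)
s$annotate$percent        # 1 29 70          (promoter/gene body/intergenic, %)
s$cobind$fraction_a       # 0.6              (TF-A peaks co-bound by TF-B)
s$cobind$conditional$fraction  # 0.7 0.5 0.5 0.5 per chromatin state
s$profile$median_fold     # 2.999424         (SE/TE median density fold)
s$interactions$fractions  # 0.6 0.3 0.1      (P-P / P-E / other)
s$interactions$mediated_fraction  # 0.4      (TF at an anchor)
c(s$de$n_up, s$de$n_down) # 120 80
```

Every number above is a planted parameter of the generator, recovered exactly
by the pipeline; the manifest (`bundle/manifest.json`) records the ground
truth per entity. On real data the same calls take your BED/bedGraph/TSV
paths via `run_config()` or a YAML file via `read_run_config()`. A thin shell
entry point ships in `inst/cli/selink`:

```sh
Rscript inst/cli/selink simulate --seed 1 --out bundle
Rscript inst/cli/selink run --config run.yaml
```

The resampling null directly:

```r
sizes <- read_chrom_sizes("bundle/genome.chrom.sizes")
tfa <- read_bed("bundle/tfa_peaks.bed")
tfb <- read_bed("bundle/tfb_peaks.bed")
overlap_ci(tfa, tfb, sizes, n_draws = 100, seed = 1)
#> overlap_ci (interval mode): observed 1200 of 2000 query intervals;
#> null 95% CI [75, 105] from 100 draws; empirical p = 0.009901
```

The observed co-binding (1200 of 2000 peaks) sits far above the null interval
of about 75–105 expected by chance, so the co-binding is called enriched with
the smallest p the add-one rule allows at 100 draws.

## Package layout

* `R/genomic-core.R` — interval model, BED/bedGraph/gene-table I/O, overlap
  and shuffle engine
* `R/peak-state.R`, `R/signal-density.R`, `R/enhancers.R`, `R/cobinding.R`,
  `R/interactions.R`, `R/expression.R` — the analysis stages
* `R/simulate.R` — synthetic-study generator and `degrade()` robustness fixture
* `R/pipeline.R` — staged orchestration, YAML config, JSON run report
* `vignettes/selink-methods.Rmd` — the methods account: models, defaults,
  design decisions, limitations
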