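# breakscape

Integrative analysis linking recurrent DNA double-strand breaks (DSBs) to
chromosome structural rearrangements, copy-number change, gene-feature
enrichment, expression changes near breaks, and survival-relevant
biomarker stratification.

## The problem

Cancer genomes carry gross structural alterations, and recurrent
spontaneous chromosome breakage is a candidate mechanism behind them.
Testing that hypothesis means asking, on a cancer cell line and a matched
non-cancer control, whether the breakpoints of structural variants (SVs)
and the boundaries of copy-number variants (CNVs) coincide with
independently mapped DSB hotspots — and whether genes implicated by that
concordance change expression and stratify patient outcome. `breakscape`
is for computational biologists who want that whole chain as composable,
tested R functions rather than a one-off collection of scripts.

## What it computes

- **DSB peak calling** from binned Break-seq coverage with per-bin
  copy-number normalization against matched DNA-seq
  (`normalize_by_copy_number()`, `call_peaks()`). Peaks are tested against
  a Poisson local background,
  `lambda = max(genome mean, 5 kb window, 10 kb window)` (candidate bin
  excluded), with genome-wide Benjamini–Hochberg control.
- **Replicate consensus and cross-line partition**
  (`consensus()`, `partition()`, `density_per_chromosome()`): the per-base
  intersection over all replicates, then common vs line-specific sets with
  exact arithmetic, `|common| + |specific| = |consensus|`.
- **CNV segmentation** of 15 kb binned counts (`bin_and_log2()`,
  `segment()`, `call_segments()`, `cnv_boundaries()`): recursive binary
  segmentation on the two-sample t statistic (accept when |t| ≥ 5, both
  sides ≥ 5 bins), loss/gain calls at ∓0.3 log2 units.
- **Paired SV breakpoint bookkeeping** (`load_bedpe()`,
  `classify_and_tally()`, `sv_delta()`): contig filtering, intra/inter
  classification, per-chromosome tallies, Circos-style pair matrix.
- **DSB × SV/CNV concordance** (`dsb_sv_overlap()`, `region_report()`,
  `dsb_cnv_overlap()`, `permutation_null()`): junction-end overlap counts
  with a length- and chromosome-preserving permutation null,
  `p = (1 + #{null ≥ obs}) / (n_perm + 1)`.
- **Feature enrichment** (`classify_peaks()`, `feature_distribution()`,
  `fisher_exact_2x2()`, `nearest_gene()`): priority-ordered peak
  classification and an exact 2×2 Fisher test (minimum-likelihood
  two-sided, log-space summation).
- **Differential expression** (`normalize_counts()`, `anova_de()`,
  `link_de_to_dsb()`): log2(CPM+1), per-gene one-way ANOVA, BH, tiered
  fold-change calls, and the join of DE genes to DSB proximity.
- **Survival stratification** (`km_estimate()`, `logrank()`,
  `optimize_cutoff()`): product-limit curves, the log-rank test with
  `chi² = (O1 − E1)²/V` and `HR = (O1/E1)/(O2/E2)`, and data-driven marker
  cut-off optimization over the 10th–90th percentile splits with optional
  permutation correction.
- **A synthetic-data generator** (`simulate_experiment()` and friends)
  that plants all of the above — hotspots, a one-arm partial deletion with
  an intact ~300 kb pericentromeric stub, junctions co-located with
  hotspots, expression fold changes near line-specific breaks, and a
  survival threshold — so every stage has recoverable ground truth.

## Worked example

```r
library(breakscape)
cfg <- pipeline_config(sim = sim_config(seed = 42), n_perm = 100)
report <- run_pipeline(cfg, outdir = "breakscape_out")

report$dsb$consensus
#>  A  B
#>  9 24
```

Line B (the cancer analog) has 24 consensus DSBs against 9 in the control:
every planted hotspot, and nothing else, survives the every-replicate
consensus at q ≤ 0.05.

```r
str(report$dsb$partition)
#> List of 4
#>  $ common    : int 6
#>  $ a_specific: int 3
#>  $ b_specific: int 18
#>  $ b_common  : int 6

report$cnv$boundaries$B
#>    chrom     pos
#> 1 chr16a 2310000
#> 2 chr16a 4155000
```

The partition recovers the planted 6 shared / 3 A-specific / 18 B-specific
hotspots, and CNV segmentation of the line-B DNA-seq track places both
deletion boundaries exactly at the planted edges (the intact
pericentromeric stub ends at 2,310,000; the deleted mid-arm ends at
4,155,000). Line A shows no boundary.

```r
report$concordance$region$text
#> [1] "4 of 5 intra junctions and 5 of 6 inter junctions"
report$concordance$null$p
#> [1] 0.00990099
round(report$sv$delta$percent_change, 1)
#> [1] 35.4
```

In the pericentromeric stub, 9 of 11 SV junction ends coincide with called
DSBs — the planted concordance — and that co-location is significant under
the permutation null. The cancer analog carries 35.4% more paired variants
than the control.

```r
report$de$linked$gene_id
#> [1] "gene_0606" "gene_0607" "gene_0608" "gene_0611" "gene_0612" "gene_0613"
lapply(report$survival, round, 3)
#> $cutoff
#> [1] 122.112
#> $p
#> [1] 0
#> $hazard_ratio
#> [1] 2.163
```

Exactly the six planted DSB-proximal genes (two up, four down) survive the
DE-near-DSB join, and the survival cut-off optimizer lands at marker value
122.1 — the 60th percentile where the hazard ratio of 2.5 was planted
(estimated 2.16 on this cohort).

A thin command-line wrapper is installed at
`inst/scripts/breakscape_pipeline.R`
(`Rscript breakscape_pipeline.R --config cfg.yaml --outdir out/`).

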