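---
title: "Methods: linking recurrent DNA breaks to structural rearrangements"
author: "breakscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking recurrent DNA breaks to structural rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

Cancer genomes accumulate large structural changes — deletions,
amplifications, translocations — and one proposed driver is recurrent
spontaneous chromosome breakage. Testing that idea requires integrating
several assays measured on the same pair of cell lines (a cancer line and a
matched non-cancer control):

* **Break-seq**, a coverage assay whose peaks mark recurrent double-strand
  break (DSB) hotspots;
* **whole-genome DNA-seq**, which yields both copy-number profiles and
  paired structural-variant (SV) breakpoints;
* **RNA-seq**, to ask whether genes near breaks change expression;
* **patient survival cohorts**, to ask whether genes implicated by the
  genomic analysis stratify clinical outcome.

`breakscape` implements that integration as a tested pipeline. Because the
interesting claims live at the *intersections* of these data types (a DSB
inside a rearrangement junction, an expression change immediately
downstream of an intact pericentromeric stub), every stage is exercised
against a synthetic experiment with planted ground truth, so the whole
chain — peak calling through survival stratification — has recoverable
answers.

# The synthetic experiment

`simulate_experiment()` builds a two-chromosome toy genome (`chr16a`, 6 Mb,
modelled on a chromosome-16-like geometry; `chr10a`, 5 Mb, a translocation
partner) and plants:

* **DSB hotspots** (400 bp, 8-fold read enrichment): shared hotspots
  concentrated in a 300 kb pericentromeric stub of `chr16a`, cancer-line
  ("B") specific hotspots in the stub, across the mid-arm, and distally,
  and a few control-line ("A") hotspots. The 8-fold enrichment over a
  Poisson background of 5 reads per 100 bp bin puts hotspots comfortably
  but not trivially above background at shallow coverage.
* **A hemizygous mid-arm deletion** on `chr16a` in line B only, spanning
  the centromere-proximal part of the q arm, with the 300 kb stub and the
  distal arm intact — the copy-number geometry of an early luminal-type
  16q loss.
* **Paired SV junctions** whose stub-side ends mostly coincide with
  hotspots: 4 of 5 intra-chromosomal ends and 5 of 6 inter-chromosomal
  ends in the stub fall inside a planted hotspot, a deliberately imperfect
  concordance so that the reporting layer has something non-trivial to
  count. Background junctions elsewhere bring the two lines' totals to 48
  (A) and 65 (B), a ~35% excess in the cancer analog.
* **Expression changes**: three genes immediately downstream of the stub
  and two more genes elsewhere are up-regulated (planted log2 fold +5),
  four genes down-regulated (−5), with the six non-stub genes placed so a
  line-B-specific hotspot sits inside the gene body (distance 0 for the
  nearest-gene join). The planted magnitude is 5, not 4, by design: genes
  reported above a |log2FC| > 4 threshold must have true effects exceeding
  the threshold by more than the measurement noise (~0.33 log2 units at
  n = 4, dispersion 0.1), otherwise threshold censoring halves their
  recovery.
* **A survival cohort** (n = 800) with log-normal marker expression, an
  exponential event process whose hazard is multiplied by 2.5 above the
  marker's 60th percentile, and independent exponential censoring at 0.4
  times the baseline hazard (`censoring_rate` is expressed as a hazard
  multiple; 0 disables censoring).

All randomness flows from one master seed through named substreams
(`coverage/<assay>/<line>/<rep>`, `expression`, `survival`, …) via a
31-bit string hash, so each stage can be regenerated independently and
every output file is byte-identical under a fixed seed.

The toy genome is deliberately gene-dense (1500 genes of ~3 kb mean span
over 11 Mb). This keeps the *composition* effects of counts-per-million
normalization at realistic magnitude: with very few genes, a handful of
strong fold changes visibly shifts library totals and biases every other
gene's estimated fold change, which no real transcriptome exhibits.

What the generator does **not** emulate: read-level data (no FASTQ, no
alignment, no sequencing-error model), GC or mappability bias in the
default tracks (the GC correction is exercised on purpose-built biased
fixtures), fragment-size effects, clustered/adjacent hotspot interference,
chromatin context, and any relation between the planted expression changes
and the planted copy-number change. Passing tests therefore demonstrate
that the *algorithms* recover planted structure under their stated noise
models — not that the assays behave this cleanly in real cells.

# Stage-by-stage models

## Copy-number normalization and peak calling

Break-seq coverage confounds breakage with DNA dosage: a hemizygous
deletion halves read depth. `normalize_by_copy_number()` divides each bin
by `max(cn_ratio, 0.25)`, where `cn_ratio` is the matched DNA-seq count
smoothed by a 51-bin running median and scaled by the genome-wide median.
The floor (0.25) caps the inflation of near-zero-coverage bins at 4×. Two
numerical caveats are documented deliberately: the running median of small
Poisson counts is biased low (the median of Poisson(2.5) is 2), so
normalized means inside deep deletions can overshoot by ~10–25%; and
normalization rescales rather than conserves total counts.

`call_peaks()` is a transparent Poisson local-background caller in the
MACS-family style: each bin's count is tested against
`lambda = max(genome-wide mean, mean of 5 kb window, mean of 10 kb window)`
with the candidate bin excluded from its own background; p-values are
upper-tail Poisson probabilities (at `ceiling(count)` for non-integer
normalized counts); Benjamini–Hochberg correction is applied genome-wide
(one experiment-wide error rate, not per chromosome); significant bins
(q ≤ 0.05) merge across gaps ≤ 500 bp; peaks narrower than 2 bins (200 bp
at the default binning, matching the ~400 bp scale of observed DSB peaks)
are discarded. Because the local background adapts *within* a deletion,
normalization mainly equalizes peak scores and signal means across dosage
levels; its effect on recall is modest for a local-lambda caller, and the
tests assert non-degradation plus high absolute recall rather than a
dramatic rescue.

## Consensus and partition

"A DSB supported by every replicate" is operationalized as the per-base
intersection of the replicate indicator functions, merged and filtered to
a 50 bp minimum width. This rule is order-independent and brute-force
checkable base by base, which the tests exploit. Cross-line commonality
uses a 1 bp minimum overlap by default (config-exposed); commonality is
counted from one side so that `|common| + |specific| = |consensus|` holds
exactly — reported interval counts always reconcile.

## CNV segmentation

Binned counts (15 kb) are log2-transformed against the genome-wide median
with a 0.5 pseudo-count; optional GC detrending uses a running median of
count against GC, rescaled to preserve the overall median. Terminal
partial bins are rescaled to full-bin equivalents before the log ratio —
otherwise every chromosome whose length is not a multiple of 15 kb ends in
a spurious "loss". Segmentation is recursive binary splitting on the
two-sample pooled-variance t statistic: accept the best split (leftmost on
ties) iff |t| ≥ 5 and both sides hold ≥ 5 bins; afterwards adjacent
segments with |Δmean| < 0.1 merge left-to-right. The procedure is
deterministic, invariant to adding a constant, and its segment means are
exactly the member-bin means. Loss/gain calls use ±0.3 — between 0 and
log2(0.75) ≈ −0.415, the expected ratio of a one-copy loss in a diploid
bulk — and boundaries are emitted between segments that change call or
differ by ≥ 0.3.

## SV bookkeeping and concordance

Paired breakpoints arrive as BEDPE (a minimal reader is included since the
standard R track importers do not parse BEDPE); the breakpoint coordinate
of each end is the per-end interval start, ends are canonically ordered,
and records touching chrY, chrM, or unassigned contigs (name containing
"_" or prefixed "Un") are dropped and counted. Tallies count each
intra-chromosomal event once and each inter-chromosomal event on both
partner chromosomes, with a symmetric zero-diagonal pair matrix (the table
behind a Circos plot).

Concordance counts junction *ends*, not whole events: a DSB hits an end
iff the end's coordinate lies in `[start − w, end + w)`. The default
window is 0 for SV ends (direct overlap) and one CNV bin (15 kb) for CNV
boundaries, whose positions are only bin-resolved. Expectation under
chance co-location is calibrated by a permutation null that re-draws DSB
start positions uniformly within their chromosome, preserving lengths and
non-overlap by re-partitioning the free space between intervals (an exact,
rejection-free equivalent of resampling until no collision). The
empirical p uses the add-one rule, `(1 + #{null ≥ obs}) / (n_perm + 1)`,
so it is never zero and is slightly conservative.

## Feature enrichment

Each peak gets exactly one feature class by priority: exon > 5′UTR >
3′UTR > promoter > downstream > intron > intergenic, first class with
≥ 1 bp overlap. Promoter and downstream windows default to 2 kb
(strand-aware; both config-exposed — these spans are conventions, not
measurements). The intronic-enrichment test is a 2×2 Fisher exact test
implemented directly by log-space summation of hypergeometric
probabilities; the two-sided p follows the minimum-likelihood definition
standard in scientific software (sum over tables no more probable than the
observed one, with a 1e-7 relative tolerance for floating-point ties), and
a one-sided upper tail is available via `alternative = "greater"`. On
small tables the implementation agrees with exhaustive enumeration to 12
digits.

## Differential expression

The expression model is intentionally the simple one: log2(CPM + 1)
normalization, per-gene one-way ANOVA across the two lines (equal to the
squared pooled t at two groups), BH correction, and tiered fold-change
calls (|log2FC| thresholds 1, 3.5, 4 as presets; the fold change is the
difference of group means of log2(CPM + 1)). No dispersion shrinkage or
moderation is applied, and that has a measurable cost at n = 4: the far
tail of the unmoderated statistic is anti-conservative (null p ≤ 0.001
occurs at ~7× nominal under NB noise), so FDR control at the weakest fold
tier is approximate. The recovery benchmark therefore filters at half the
planted magnitude (|log2FC| > 2), a point lying on a wide plateau where
sensitivity and false discovery are both clean, rather than at the
knife-edge of either the noise scale or the planted effect. Genes near
line-specific DSBs are joined to the DE table by `nearest_gene()` within
5 kb (distance 0 on gene-body overlap, lexicographic tie-break).

## Survival

`km_estimate()` is the textbook product-limit estimator; `logrank()`
accumulates observed minus expected events and the hypergeometric variance
over distinct event times, with `chi_square = (O1 − E1)² / V` on 1 df and
the hazard ratio `(O1/E1)/(O2/E2)` (high-marker group over low).
`optimize_cutoff()` formalizes "data-driven grouping": evaluate the
log-rank test at every distinct marker value whose split keeps the
low-group fraction within the 10th–90th percentiles, return the minimum-p
cut-off (ties resolve toward the median). That minimum is selection-biased
by construction; an optional permutation correction (off by default, to
mirror how such cut-offs are typically reported) re-optimizes on
marker-shuffled cohorts and returns the empirical p of the observed
minimum. The tests document both halves: the uncorrected minimum p is
stochastically small under the null, the corrected p is approximately
uniform.

# Problem sizes and numerical choices

The test and acceptance fixtures use: an 11 Mb genome at 100 bp coverage
bins (110,000 bins per track), 50-hotspot peak-recovery tracks of 21,000
bins, 100,000-bin null tracks for false-positive calibration, 100-interval
consensus fixtures checked base-by-base, 100 random genomes for CNV
boundary recovery, 200 seeds × 199 permutations for null-p uniformity
(Kolmogorov–Smirnov at α = 0.01), 2000-gene expression matrices with 100
planted effects, and 100 cohorts of n = 800 for cut-off recovery. These
sizes were chosen so each stochastic check has enough resolution for its
stated threshold (e.g. 3-SE bands on binomial fractions) while the full
suite stays comfortably runnable on a laptop.

Other numerical choices: Poisson tails for non-integer normalized counts
are evaluated at `ceiling(count)`; zero-count bins are assigned p = 1;
q-score reporting floors q at 1e-300 before −log10; the segmentation
t statistic treats a zero pooled variance with unequal means as an
immediate accept (infinite t) and with equal means as t = 0; degenerate
splits (constant marker, empty group) raise errors rather than returning
NAs.

# Known limitations

* The peak caller is not a reimplementation of any published caller;
  bit-compatibility with MACS2 is a non-goal, and fragment-model features
  (paired-end shifts, strand cross-correlation) are absent.
* Copy-number segmentation is single-sample binary segmentation; it does
  not estimate ploidy, allele-specific state, or use external mappability
  tracks.
* The expression layer deliberately uses unmoderated ANOVA; at small n its
  extreme tail is optimistic, as quantified above.
* The survival layer implements dichotomization at an optimized cut-off
  because that is the procedure under study; for inference in real
  cohorts, the permutation-corrected p (or a pre-registered cut-off)
  should be preferred, and continuous-covariate models (Cox) are out of
  scope.
* Real consensus/partition counts from published experiments are not
  reproducible from interval arithmetic alone (published common/specific
  tallies need not reconcile additively); the package's partition enforces
  exact arithmetic instead of emulating any unstated merging rule.
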