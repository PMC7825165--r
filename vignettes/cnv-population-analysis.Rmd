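---
title: "CNV population analysis from windowed read depth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV population analysis from windowed read depth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpop)
library(dplyr)
```

# The problem

Copy number variants (CNVs) — deletions and duplications of kilobase-scale
genomic segments — are a major class of structural variation in livestock
genomes and can carry phenotypic effects that SNPs miss. In whole-genome
resequencing, the primary CNV signal is *read depth*: the number of aligned
reads falling into fixed windows (here 100 bp) is, after normalization,
proportional to the local copy number. `cnvpop` implements the complete
population-scale analysis chain downstream of alignment:

1. per-individual CNV calling from windowed depth (normalization,
   multi-scale segmentation, significance testing, filtering),
2. merging calls across a cohort into copy number variable regions (CNVRs)
   with deleted/conserved/duplicated classification,
3. interval comparison against external CNVR catalogues, QTL tables and
   gene annotations,
4. the V~ST~ statistic for scanning CNVRs for population differentiation
   (e.g. horned versus polled sheep groups), and
5. relative copy number from qPCR cycle thresholds (2 × 2^−ΔΔCt^) with
   concordance scoring against predicted CNVR states.

Because resequencing data for a full cohort is far too large for routine
verification, the package is organised around a first-class synthetic-data
generator that emulates the statistical structure the downstream stages
assume; every stage is tested against planted ground truth or a brute-force
oracle.

# The synthetic depth generator

`population_design()` + `plant_truth()` + `simulate_depth()` produce a
cohort of per-window depth tracks:

* **Counts.** Window counts are negative binomial with mean
  `mean_depth × CN / 2` and size parameter `overdispersion`; `Inf`
  recovers the Poisson. Defaults: `mean_depth = 30` reads per 100 bp
  window (the coverage scale of modern resequencing studies) and size 20,
  i.e. mildly overdispersed — variance ≈ 75 at the diploid mean of 30.
  Real depth is overdispersed by mapping artefacts and library effects;
  size 20 reproduces that inflation without burying the copy-number signal.
* **Truth sets.** CNV loci are placed non-overlapping, snapped to window
  boundaries (the caller's native resolution, which makes recovery tests
  exact), with lengths uniform over 1.2–8 kb and integer copy numbers
  drawn from {0, 1} for deletions and {3, 4} for duplications.
  `duplication_fraction = 0.1` reflects the strong excess of deletion
  calls in read-depth call sets. Shared loci segregate in every group
  (carrier frequency 0.5 by default); differentiated loci segregate at
  0.9 in one group and 0.1 in the other unless configured otherwise.
* **q0.** Each window carries a fraction of zero-mapping-quality reads,
  Beta-distributed around `q0_baseline = 0.05`; `q0_inflate` marks
  intervals that emulate repeat-rich regions (mean q0 near 1) so the q0
  filter can be exercised.
* **Determinism.** The design seed is mandatory. Each individual draws
  from a sub-seed derived from the design seed and its index, so a
  profile does not depend on how many other individuals were simulated.

What the generator does *not* emulate: GC-dependent coverage waves,
mappability structure beyond the q0 channel, alignment-level artefacts
(soft-clips, split reads), and inter-library depth differences. Passing
recovery tests therefore demonstrate correctness of the algorithms under
the stated noise model, not calling performance on real genomes.

# The read-depth caller

**Normalization.** `normalize_depth()` rescales counts to
`rd = 2 × count / m` so the diploid expectation is 2.0. `m` is a
10%-trimmed mean of the autosomal windows: with a plain mean, megabase-scale
events would drag the baseline and bias every CN estimate; the trimmed mean
is insensitive to them (`trim = 0` restores the plain mean, under which
`mean(rd)` is exactly 2). Sex chromosomes are rescaled but excluded from
`m`, since their ploidy differs; calls on them are flagged.

**Segmentation.** `segment_depth()` partitions each chromosome into
contiguous segments of near-constant `rd`:

1. Gaussian-kernel smoothing over the window index at bandwidths
   h ∈ {2, 4, 8, 16} windows;
2. a breakpoint wherever the absolute difference of adjacent smoothed
   values exceeds `t` standard deviations *of that difference*:
   the threshold is `t·σ̂·c_h`, where σ̂ is the MAD of `rd` and `c_h`
   propagates σ̂ through the difference-of-smoothed kernel. Normalizing
   per scale is essential: smoothing attenuates noise faster than it
   attenuates a step edge, so a single absolute threshold that controls
   false breakpoints at h = 2 is blind to single-copy steps at every
   scale. Within a run of threshold exceedances one breakpoint is placed
   at the steepest point; coarser scales only add breakpoints at least h
   windows away from existing ones, keeping localisation at the finest
   detecting scale;
3. adjacent segments whose means differ by less than `merge_eps = 0.3`
   (about one-sixth of a copy) are merged iteratively, closest pair first.

The default `t = 3.5` was fixed during algorithm development on simulated
30× tracks as the point where planted single-copy events ≥ 1 kb are
recovered essentially completely while pure-diploid 5 Mb genomes yield
zero surviving calls. The procedure is deterministic: identical inputs give
identical segmentations.

**Calling and filtering.** Segments with |mean rd − 2| > 0.5 become
candidates. Each candidate gets: `cn` = segment mean `rd` (the diploid
scale directly); `e_val` = two-sided one-sample t-test p-value of the
segment's windows against the individual's genome-mean `rd`
(single-window segments are untestable and get `e_val = 1`); `q0` =
read-weighted mean zero-MAPQ fraction (0 when the segment holds no reads
at all, as in a clean homozygous deletion — there are no reads to be
unreliable). `filter_calls()` then retains calls with p < 0.01, span
strictly greater than 1 kb, and q0 < 0.5 — the standard read-depth
filtering regime. The 1 kb bound is exclusive: a call spanning exactly
1000 bp is removed.

# CNVRs: merging, classification, summaries

`merge_cnv_calls()` aggregates overlapping calls from different
individuals into CNVRs — connected components of the ≥ 1 bp-overlap graph.
Coordinates are 0-based half-open throughout, which makes the abutting
case crisp: `[100,200)` and `[200,300)` share no base and are *not*
merged. The merge is delegated to `IRanges::reduce(min.gapwidth = 0L)`
and is verified in the test suite against a per-base coverage-mask oracle
on random instances.

`classify_cnvrs()` assigns each supporting individual a state from its CN
estimate — deleted below 0.4, conserved in [0.4, 1.6] (inclusive bounds),
duplicated above 1.6. These bounds sit on the diploid scale, so "deleted"
means near-homozygous loss; heterozygous deletions (CN ≈ 1) are
*conserved* under this rule, which matters for qPCR concordance (below).
An individual with several calls in one region gets their length-weighted
mean CN — the least arbitrary aggregation where none is prescribed. Region
type is deletion/duplication when only that state occurs among
non-conserved supporters, and "both" when the two coexist.

`summarize_cnvrs()` produces the familiar CNV-map table: counts by type,
total length (Mb), mean length (kb), percent of the analysed genome
(denominator: the summed raw chromosome lengths of the layout actually
analysed), per-chromosome counts, and the R² of the OLS regression of
per-chromosome count on chromosome length. Full precision is kept in the
object; `glance()` and `render_summary_table()` round to two decimals,
matching the printed convention of published tables (`round_half_up()`,
since printed tables round half away from zero, unlike R's `round()`).

`group_presence()` reports in which groups each CNVR segregates and the
full Venn partition; the cell counts always sum to the number of CNVRs.

# Interval comparison

`overlap_sets()` reproduces the accounting used when a new CNV map is
compared against earlier catalogues: a *reference* record counts as
overlapped when it intersects any query CNVR by ≥ 1 bp, and the percentage
is taken over the reference catalogue's size. `overlap_qtl()` counts query
CNVRs hitting ≥ 1 QTL and the distinct QTL labels hit.
`annotate_genes()` captures genes whose length is covered ≥ 50% by a CNVR
(inclusive); the fraction is anchored on the *gene* length, the natural
reading of "overlapped genes". External files may declare a `one-based`
dialect and are converted on load; all internal arithmetic is 0-based
half-open. All three operations are tested against brute-force per-base
oracles on ≥ 100 random toy instances.

# V~ST~

For two groups with sizes n₁, n₂, V~ST~ = (V~T~ − V~S~)/V~T~, where V~T~
is the sample variance of the pooled signal and
V~S~ = (n₁v₁ + n₂v₂)/(n₁ + n₂) the size-weighted mean within-group sample
variance. Choices made explicit:

* sample variances use the n − 1 denominator (groups are small; the
  worked-example oracle in the tests assumes the same);
* V~T~ = 0 ⇒ V~ST~ = 0: a monomorphic site is by definition
  undifferentiated;
* the per-window signal is *normalized read depth* (diploid = 2).
  Array-based formulations use SNP log-R ratios; resequencing has no LRR,
  and normalized depth is its direct copy-number analogue;
* `cnvr_vst()` averages per-window V~ST~ values (unweighted) across the
  windows of a CNVR;
* `select_candidates()` supports both a top-fraction rule (default 5%,
  `ceiling(0.05 n)` records) and a top-k rule (e.g. top five), because
  both conventions are in circulation; ties at the cut are kept and the
  applied threshold is reported.

On simulated cohorts with a fully differentiated homozygous deletion
(carriers only in one group), mean CNVR V~ST~ exceeds 0.8 across seeds and
the locus is the top-5% pick against diploid decoy regions; with no
differentiated loci, CNVR V~ST~ stays well below 0.5.

# qPCR copy number and concordance

`qpcr_copy_number()` averages triplicate Ct values on the Ct scale (the
standard practice), forms ΔCt = Ct~target~ − Ct~reference~ per sample,
ΔΔCt against a user-designated diploid calibrator sample, and reports
CN = 2 × 2^−ΔΔCt^. The identities CN(0) = 2, CN(1) = 1, CN(−1) = 4 and
the product law CN(x)·CN(−x) = 4 hold exactly. Replicate SDs above a QC
bound flag the measurement without dropping it.

`qpcr_concordance()` maps qPCR CN to states with the same 0.4/1.6 bounds
and confirms a target when states agree with the predicted region type in
more than half of its assayed samples (configurable). Since "agreement"
is not standardised, two modes are provided: `strict` (state match only)
and `lenient`, where a predicted deletion is also confirmed by a
heterozygous-range value (CN < 1.6) — without it, a true single-copy loss
assayed at CN ≈ 1 would count against a deletion call. The mode is
recorded in the output.

# Pipeline, configuration, determinism

`cnv_config()` holds every constant in one validated structure — window
size (100 bp), filter thresholds (0.01, 1 kb, 0.5), CN class bounds
(0.4/1.6), V~ST~ cutoff (5%), seed — with unknown keys rejected
fail-fast and lossless YAML round-tripping. `run_cnv_pipeline()` executes
simulate (optional) → call → filter → merge → classify → summarize →
compare → V~ST~ → report, writes each stage's TSV plus a JSON manifest
(seed, parameters, per-stage record counts), and is byte-identical on
rerun with the same config. The package has no shell entry point by
design: its users drive it from R, and the functions plus this vignette
are the interface.

# Numerical and degenerate-input policy

* Coordinates: 0-based half-open internally; 1-based inclusive only
  accepted at input boundaries via the declared dialect.
* Trailing partial windows are dropped; chromosome lengths are kept both
  raw (reporting denominators) and in whole windows (analysis extent).
* Empty inputs return typed empty results (empty truth set, empty call
  set, all-zero summary with R² reported unavailable) rather than errors;
  malformed records (end ≤ start, negative CN, unknown individuals or
  groups) fail with the offending record identified.
* Single-window segments are never significant; segments with zero
  within-variance get p = 0 or 1 by exact mean comparison.
* Report rounding is half-away-from-zero at two decimals, applied only at
  the rendering boundary.

# Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use 2 Mb single-chromosome
genomes with eight planted CNVs per seed (20 seeds) for caller recovery,
5 Mb diploid genomes (4 seeds) for the false-call allowance, and 0.5 Mb
cohorts of eight individuals (10 seeds) for the V~ST~ sweep. These sizes
give stable Monte-Carlo estimates (≥ 120 pooled events) while keeping a
full run in tens of seconds; the statistics are scale-free in genome
length, so nothing but Monte-Carlo error changes on larger toys.

# Known limitations

* The segmentation is an explicit, deterministic stand-in for a
  mean-shift read-depth segmenter; it is not a reimplementation of any
  specific caller's internals, and its e-value is a plain t-test p-value,
  not a multiple-testing-adjusted e-value.
* GC normalization is not applied by default (the generator is GC-flat);
  the hook in `normalize_depth()` is limited to the trimmed-mean choice.
* V~ST~ significance is by ranking only; no permutation test is provided.
* Liftover between assemblies is out of scope — external interval sets
  must already be on the analysis assembly.
* The bundled published summary tables are transcriptions of printed
  numbers and are used only for report arithmetic, never as measurements.
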