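---
title: "Methods: peak consensus, annotation and expression-network statistics in cistromix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak consensus, annotation and expression-network statistics in cistromix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromix)
```

cistromix implements the computational side of a common study design in
regulatory genomics: a transcription factor (here named after FOXM1, the
forkhead-box G2--M regulator) is profiled by ChIP-seq in two replicates and
in a second cell type, its binding regions are annotated to genes, and the
expression of the resulting target-gene panel is then measured in clinical
tissue by digital transcript counting and related back to the factor by
correlation and group statistics. This vignette explains each model, its
assumptions and tunable parameters, and the design choices made where the
published rules left room.

## Coordinates and the overlap statistic

All intervals are 0-based, half-open internally; BED input is taken as-is and
GTF input is shifted by one on the start at the I/O boundary. The reciprocal
overlap measure used throughout is the fraction of the *smaller* region
covered by the intersection,

$$f(a, b) \;=\; \frac{|a \cap b|}{\min(|a|, |b|)},$$

which is symmetric, equals 1 for nested regions, and is 0 across
chromosomes. When the two regions have equal length the "smaller" is
ambiguous but the value is identical either way, so no tie-break is needed.

## Replicate consensus ("high confidence" peaks)

`replicate_consensus()` encodes a three-part rule:

1. a replicate-1/replicate-2 peak pair *overlaps* when $f \ge$ `min_frac`
   (default 0.5);
2. a pair *qualifies* when at least one of its two peaks has FDR < `max_fdr`
   (percent scale, default 10) **and** tag density > `min_td` (default 15) —
   both inequalities strict, exactly as such thresholds are printed by
   MACS-style callers;
3. every connected component of the qualifying-pair graph containing peaks
   from both replicates becomes one consensus region.

Step 3 is a design decision: published descriptions of replicate-overlap
filtering are silent about one-to-many overlaps. Connected components make
the result deterministic and order-independent, and a chain of mutually
overlapping peaks collapses into one region rather than being double
counted. The consensus region is reported as the union interval of its
members — the conservative, reproducible geometry — with the summit taken
from the member with the highest tag density (ties by peak id). The gate in
step 2 is applied per pair, not per component: a component survives if any of
its edges survives, which matches the reading that a region is kept when it
is "supported in at least one replicate" at the required quality.

Candidate pairs are found with `GenomicRanges::findOverlaps()` and the
components with `igraph`; the test suite checks the whole operation against
an independent brute-force all-pairs/BFS oracle on random instances, and
checks symmetry in the replicates and monotonicity in `min_frac`.

The companion `filter_high_sensitivity()` implements the stricter
pooled-reads filter (FDR < 10, TD > 30, both strict): when reads from both
replicates are pooled and peaks recalled, tag densities roughly double, and
the higher tag-density bar compensates. `compare_peak_sets()` classifies the
peaks of two cistromes as shared or unique under the same overlap statistic;
the counts are exhaustive and disjoint by construction.

## Peak-to-gene annotation

`assign_nearest_gene()` uses two clauses, deliberately different in what
part of the peak they test:

* the **TSS window** clause tests the *summit*: a gene is a candidate when
  the summit lies within `upstream` (default 5000) bp before to `downstream`
  (default 1000) bp after its strand-oriented TSS;
* the **promoter proximity** clause tests the *whole peak interval*: a gene
  is a candidate when the peak comes within `promoter_pad` (default 1000) bp
  of its core promoter.

The core promoter is defined as the 5' UTR plus 1 kb upstream of the TSS.
Where a gene model carries no UTR annotation the TSS alone is used as the
downstream edge. Among candidates, the smallest absolute summit-to-TSS
distance wins; exact ties go to the lexicographically smallest gene id (a
deterministic choice; the underlying convention is unpublished). Because the
proximity clause can legitimately implicate more than one gene, the
runner-up candidates are reported in an `alternates` column rather than
discarded silently. Distances are signed in gene orientation, negative
upstream, so on the minus strand "upstream" means higher coordinates.

`feature_distribution()` classifies each summit with the precedence
core promoter > exon > intron > 1 kb downstream of the gene end > distal
intergenic. A precedence is required because the classes overlap (a 5' UTR
is also exonic); the promoter is given priority to match the analytical
emphasis on promoter-proximal binding. The background is the genome-wide
base-pair occupancy of the same classes under the same precedence, computed
by interval subtraction (`GenomicRanges::setdiff`) so each base is counted
exactly once; both the observed and background vectors sum to 1.

## Summit-centred tag densities

`density_matrix()` counts single-base tag positions (read 5' ends) in
`2 * flank / bin_size` fixed bins centred on each summit — 200 bins at the
defaults of 5 kb flank and 50 bp bins, with bin 101 covering
`[summit, summit + 50)`. Tags are used as given, with no fragment extension
and no between-library normalisation: the matrices are intended for
within-library heatmaps (rows ordered by total signal) and mean profiles,
not for cross-sample quantitative comparison. Peaks are treated as
unstranded, so bins always run left to right in genome coordinates.

## Digital-count normalisation

`normalise()` performs the standard two-stage NanoString-style scaling.
For each stage the per-sample factor is

$$\text{factor}_i \;=\; \frac{\overline{g}}{g_i}, \qquad
  g_i = \Big(\prod_{p} x_{pi}\Big)^{1/P},$$

the arithmetic mean across samples of the per-sample geometric means of the
stage's probes, divided by this sample's geometric mean. Stage 1 uses the
positive-control spike-ins, stage 2 the chosen reference genes (the
housekeeping sets used with this assay are `ALAS1`, `GAPDH`, `HMBS` for cell
lines and `SDHA`, `ALAS1`, `GAPDH`, `HMBS`, `PARPBP` for clinical tissue).
Targeting the cross-sample mean rather than a fixed constant keeps the
output on the input scale. The exact vendor formula behind "default
settings" is not published; the mean-of-geomeans target is this package's
documented choice. Stage 2 rescales assay content (endogenous plus reference
probes) while the spike-ins keep their stage-1 values; with that convention
the operation is exactly idempotent and both probe classes sit on their
targets after one pass — a property the tests assert at 1e-9 relative
tolerance. Zero counts entering a geometric mean are floored to 1 with a
warning (zeros would otherwise annihilate the mean); endogenous zeros are
left untouched.

`zscore_by_gene()` (sample sd, $n-1$) feeds clustering heatmaps;
`fold_to_normal_median()` divides each gene by its median across normal
samples, the scale used for tumour-vs-normal boxplots, and refuses genes
whose normal median is not positive.

## Expression statistics

* **Anchor correlation** (`anchor_correlation()`): per-gene Pearson $r$
  against the anchor gene across samples, flagged at $r > 0.7$ (strict, as
  the threshold is stated). Zero-variance genes are reported as missing with
  a warning rather than silently dropped. Correlation should be computed on
  normalised log-scale expression; correlating raw counts leaves shared
  technical (lane) variation in both variables and inflates $r$.
* **Clustering** (`hierarchical_cluster()`): average-linkage agglomeration
  on $1 - r$ distance, the defaults of the classic microarray viewers; the
  published analysis names the tool but not its settings. Samples and genes
  are clustered with the same metric (the alternative was not stated; using
  one metric is the simpler, documented choice).
* **Mann–Whitney** (`mannwhitney()`): two-sided; exact U distribution when
  $n_a + n_b \le 12$ with no ties, otherwise the normal approximation with
  tie and continuity correction. Fold changes for tissue contrasts are
  ratios of group medians, consistent with the median-based boxplot
  displays.
* **Boxplots** (`boxplot_summary()`): quartiles by linear interpolation of
  order statistics (type 7); the original analysis used SPSS, whose hinge
  convention differs in small samples, so the tests use cases that are
  convention-robust. Outliers are values strictly beyond 1.5 IQR fences.
* **High/low partition** (`partition_foxm1()`): a tumour sample is "high"
  when it exceeds both mean + 2 sd and 2 x mean of the normal samples,
  strictly. Both criteria scale with a positive constant, so the labels are
  unit-invariant — a property the tests exercise.
* **Knockdowns** (`knockdown_test()`): unpaired two-tailed pooled-variance
  t-test; fold change relative to the control mean (control taken as 1),
  log2 fold for heatmaps. No multiple-testing correction is applied
  anywhere: the analyses report raw p-values with `*`/`**` marks at 0.05
  and 0.01, and the package follows that convention.
* **Venn overlap** (`venn_overlap()`): partitions two significant-gene sets
  and flags shared genes with discordant directions (the situation of a
  gene responding oppositely to two different knockdowns).

## The synthetic-data generators

`sim_config()` fixes every generator parameter; each generator is a pure
function of its config (same seed, same bytes), with an independent RNG
stream per generator so adding one does not perturb the others.

* `simulate_peak_replicates()` plants peak pairs at well-separated positions
  (20 kb spacing, so no accidental chaining) with overlap fractions cycling
  through values straddling the 0.5 cut-off and FDR/TD values drawn to pass
  or fail the gate by design; the truth table records exactly which pairs
  must survive consensus.
* `simulate_tags()` draws a uniform Poisson background plus Gaussian-shaped
  enrichment (sd 100 bp) at each summit — the simplest model that produces
  the summit-centred profile shape.
* `simulate_expression()` mirrors the clinical design: 24 normal and 58
  tumour samples by default (and 78-sample single-group cohorts for
  correlation-recovery experiments), a log2 tumour effect of 2 on the
  anchor, a 20-gene block with true latent correlation 0.8 built from the
  anchor's standardised signal, 5 anti-correlated genes at $-0.6$, 20 null
  genes, five reference genes at 5% CV, a four-fold positive-control ladder,
  and a per-sample lane factor (log2 sd 0.25) that the normalisation stage
  must remove. Counts are log-normal latent values rounded to integers:
  digital counts of moderately expressed genes are over-dispersed relative
  to Poisson, and a log-normal captures that with one parameter.
* `simulate_knockdown()` produces a three-replicate control arm plus one arm
  per configured siRNA, with per-gene log2 effects (the defaults plant
  FOXM1- and LIN9-responsive genes and one discordant gene) over 0.15 log2
  replicate noise.

What the generators do *not* emulate: mappability and GC structure in the
tag background, fragment-length effects, probe-specific hybridisation
efficiencies, batch structure beyond a single lane factor, and biological
covariance beyond the planted blocks. Passing tests therefore demonstrate
that the algorithms implement their rules correctly and recover planted
structure at realistic noise — not that the pipeline is robust to every
artefact of real libraries.

## Numerical choices and degenerate inputs

All threshold comparisons are strict, as printed. Peaks must have positive
length and contain their summit; constructors reject violations so the
overlap fraction is always well defined. Empty replicate sets make consensus
undefined (error), while an empty comparison set is legal (everything is
unique). Constant genes abort z-scoring and clustering with a named error,
but the workflow drivers skip them with a warning so one flat probe does not
kill a run. Geometric means floor zeros to 1, with a warning, before
logging. The Mann–Whitney exact/approximate switch is at total $n = 12$;
the knockdown t-test refuses arms with zero pooled variance.

Problem sizes in the test suite were chosen to finish comfortably on one
CPU while leaving the statistical assertions well powered: 100--120 random
instances for the oracle-equivalence suites (up to 50 peaks per replicate),
200 seeds for correlation recovery, and 2000 simulations for the
Mann–Whitney calibration at the 24-vs-58 cohort sizes.

## Known limitations

* Consensus counts are counts of *merged regions*; analyses that count
  replicate-1 peaks instead will differ when components are not one-to-one.
* The nearest-gene report gives one gene per peak; genes tied through the
  promoter-proximity clause appear only in the `alternates` column.
* Tag-density matrices are not library-size normalised; compare heatmaps
  only within a library.
* The positive-control normalisation stage uses a documented surrogate for
  an unpublished vendor formula; absolute normalised values may differ from
  vendor software, though relative (between-sample) structure does not.
* Clustering leaf order follows `stats::hclust`; other tools' tie-breaking
  may order leaves differently at equal heights.
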