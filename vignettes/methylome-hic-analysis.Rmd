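---
title: "Methods: bacterial 6mA methylome analysis with chromosome-conformation integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bacterial 6mA methylome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methica)
```

## Scope and model of the data

`methica` analyses N6-methyladenine (6mA) methylomes of bacteria with a
single circular chromosome. A methylome is represented as a set of
single-base methylation calls (0-based position, strand, optional motif id
and quality score), typically derived from SMRT-style base-modification
analysis. The genome is partitioned by a CDS annotation into coding and
intergenic sequence, and three families of questions are addressed:

1. **Where do methylated motifs sit?** Degenerate (IUPAC) recognition
   motifs are scanned on both strands; methylated sites are classified into
   the coding/intergenic partition; densities are summarised per class and
   per functional category (COG letter or KEGG Orthology id).
2. **Is motif usage biased between coding and intergenic sequence?**
   Observed occurrence counts are compared with expectations under a
   Markov composition model trained separately on each sequence class.
3. **Does the methylation state coincide with regulatory features and
   chromosome organisation?** Upstream regions are scanned for
   transcription-factor binding sites with exact p-values, hits are
   intersected with methylation calls, and Hi-C contact maps of two
   conditions (for instance a methyltransferase knockout against its wild
   type) are compared for unique interactions, interaction domains and
   insulation changes.

Every coordinate inside the package is 0-based and half-open; 1-based
inclusive conventions (GFF3) are converted at file boundaries only, so a
single stated convention applies to every overlap and density computation.

## Motif scanning and counting conventions

A motif is an IUPAC string with an optional palindromic partner written
`forward/reverse`; the partner must be the IUPAC reverse complement of the
forward string, and this is validated on construction. Scanning reports
every match of the forward string on the plus strand and every match of
its reverse complement on the minus strand, overlapping matches included.
A self-reverse-complementary motif therefore yields the same interval once
per strand; published motif tables count one occurrence per dyad (one
double-stranded site), so `count_motif_dyads()` deduplicates intervals
while the per-strand records remain available for per-adenine analyses.

A methylated site belongs to the coding class iff its position lies inside
at least one CDS interval, regardless of gene strand: the coding/intergenic
dichotomy is positional. Sites inside two overlapping genes count once at
class level (the class partition is exact) and once per gene in per-gene
tallies. Densities are reported per kb of class length; per-category
summaries report the *median* per-gene density so that a category ranking
is robust to single highly methylated genes.

## Markov expectation and the usage-bias statistic

Expected motif counts use a Markov model of base composition of order
*m* (default 2, configurable 0-5). The default captures near-codon
composition structure in coding sequence without sparse estimation on
bacterial-genome-scale training data; the order is deliberately not pushed
higher because a 200 kb intergenic training set estimates 4^6 transition
rows poorly. Transition probabilities are maximum-likelihood counts of
(m+1)-mers with an additive pseudocount (default 1); the initial
distribution is the empirical m-mer frequency. One model is trained on the
CDS fragments, one on the intergenic fragments, and each is evaluated on
its own class, so that the bias statistic controls for class-specific
composition.

The match probability of a degenerate motif is computed without expanding
it: order 0 multiplies per-position marginals; order >= 1 runs a positional
dynamic program over the 4^m context states, so `N`-runs in the motif cost
nothing. The expectation over a set of fragments of lengths `L_f` is
`E = sum_f (L_f - k + 1) * P(match)`, scored per strand and summed over
the two strands to match the scanner's conventions. Occurrences straddling
a class boundary are counted in neither class, consistently with the
per-fragment window count.

The usage-bias statistic is

```
b = log2(O_ig / E_ig) - log2(O_cds / E_cds)
```

negative values mean coding skew, positive intergenic skew. A difference
of log-ratios was chosen over the perpendicular distance to the diagonal
of an observed/expected scatter (the two differ by a factor of sqrt(2));
it is the simplest monotone equivalent and keeps the statistic in
interpretable log2 units. Zero observed counts are replaced by a 0.5
pseudo-observation and flagged rather than dropped.

## Enrichment statistics

Differential tables are filtered by fold change and significance before
enrichment. Two filter profiles mirror common practice: transcriptome
tables use adjusted p (`padj <= 0.05`) with a 2.0-fold change; proteome
tables use raw `p < 0.05` with a 1.2-fold change. Per functional category
a 2x2 table (differential in/out of category against the annotated
background) is tested with the two-sided Fisher exact test under the
probability-mass rule, and Benjamini-Hochberg q-values are computed across
the categories of one analysis. Both raw p (with a `significant` flag at
p < 0.05) and q are reported, since headline claims are commonly gated on
the former while the latter is the defensible quantity. Small validation
statistics for qPCR cross-checks (`2^-ddCT` relative expression, Pearson
correlation) are included so that a complete analysis needs no second
toolbox.

## TFBS scanning with exact p-values

Position weight matrices are built from equal-length binding-site sets
with background-weighted pseudocounts. Upstream regions of 50-300 bp are
extracted per gene (promoter-oriented: minus-strand genes take the
mirrored region, reverse-complemented), truncated at the nearest CDS so
that regions never overlap coding sequence; shorter regions are dropped
and counted. Each region is scanned on both strands at every offset. The
log2-odds score's null distribution under the order-0 background is
computed exactly by dynamic programming over integer-quantized scores
(quantization step 1/1000 bit, the resolution at which two scores are
considered equal); the p-value of a window is the upper-tail probability
of its quantized score. Tests verify the DP against full 4^w enumeration.
q-values are computed by BH over all scanned offsets of a run, which
approximates FIMO-style q-value machinery, and hits are kept at
`q <= 0.05`. A hit is *methylated* iff a call position lies within the hit
interval (half-open); the strictest reading of site/methylation
association. Because adjacent bases plausibly matter for protein binding,
the association window is a parameter (`flank`), with 0 as default.

Windows containing `N` are skipped and counted; a zero-variance window in
the insulation comparison (below) is treated as concordant only when both
windows are flat - the documented tie rule for degenerate inputs.

## Comparative Hi-C

Contact pairs are binned into a symmetric matrix on the circular
chromosome (the diagonal is kept; binning conserves total pair mass).
Balancing is plain iterative correction: rows and columns are divided by
their relative coverage until the coefficient of variation of row sums
falls below 1e-5 (default cap 200 iterations); all-zero bins are masked
and reported, and the per-bin biases are returned so raw counts can be
reconstructed.

Significant interactions use a distance-stratified binomial model: the
contact probability of a pair at circular distance d is the mean balanced
contact at d normalized over all tested pairs, and the p-value is the
upper binomial tail of the observed raw count given the total. This is a
simplified form of decay-conditioned significance calling without spline
smoothing or refinement passes; the published filter thresholds are
honored exactly (p < 0.01, q < 0.01, raw count > 2). The diagonal is not
tested. Tests verify the tail probabilities against direct summation.

The insulation score of bin i is the mean balanced contact in the w x w
square of pairs immediately upstream x downstream of i (default w = 10
bins), log2-normalized by its genome-wide mean. Domain boundaries are
local minima whose boundary strength - mean score over `delta_span` bins
(default 5) on each side minus the minimum, summed over both sides -
reaches `strength_min` (default 0.5 log2 units; planted-domain contrasts
of 3x produce dips of ~1.5 units, so the default separates real junctions
from noise minima by a factor of ~3). Interaction domains are the arcs
between consecutive boundaries and tile the circle by construction.

Condition-unique elements need matching rules: an interaction is unique
iff its pair passes the filters in exactly one condition; a domain is
unique iff no domain of the other condition reaches reciprocal overlap
>= 0.8 (standard domain-matching practice; parameterized). Unique
insulation regions follow the sliding-window procedure: windows (default
20 bins, step 1, circular) with Pearson r > 0.6 between the two insulation
profiles are merged as concordant, and maximal runs of the remaining bins
are reported.

## The synthetic-data generator

Every stage is validated against data with planted ground truth, because
the real measurements the pipeline was designed around are
deposit-archive-scale sequencing data. The generator emulates, at desk
scale:

* a circular chromosome (default 200 kb standing in for ~3 Mb) with
  Markov base composition (default order 0 at 46% GC, the typical
  composition of lactic-acid bacteria);
* ~100 non-overlapping genes of 500-1500 bp (~50% coding fraction) with
  alternating strands, uniform-random gaps, COG letters and KO ids drawn
  from configurable palettes;
* a palindromic 6mA motif (default `GCCAT/ATGGC`, methylated adenine at
  offset 3) written into the sequence at Poisson-placed positions with
  class-specific densities. Defaults of 0.96/0.77 occurrences per kb at a
  99% per-occurrence call rate give called-site densities of ~0.95 (CDS)
  vs ~0.76 (intergenic) per kb, the contrast scale reported for real
  *Lacticaseibacillus paracasei* methylomes. Overlapping placements are
  re-drawn (a simple alternative to an exact hard-core process; the bias
  is negligible at these densities);
* a differential table where each gene is flagged with probability
  `de_frac` (default 0.045), odds-multiplied by 8 in the planted category;
  with a category of ~10% of genes this yields an overall differential
  fraction of ~6.8%, i.e. ~196 of 2900 genes. p-values are back-filled
  consistently with the flags, because count-model internals are out of
  scope - only threshold filtering and enrichment are exercised;
* reference/test contact matrices with expected counts
  `mu = C * d^-alpha` on the circular distance (defaults C = 50,
  alpha = 1, 400 bins), three planted self-associating blocks (3x within
  boost), and test-specific contact boosts of 12x. Counts are Poisson via
  the quantile transform of one shared uniform draw per pair, so the two
  conditions are bitwise identical wherever their expectations coincide
  and differ only at perturbed pairs. Planted differential pairs sit at
  circular distances of 15-35 bins: there the decay baseline expects
  >~1.4 counts, a 12x boost drives the binomial tail below ~1e-8, and the
  spike survives BH correction over the ~8e4 tested pairs. Spikes planted
  far off the diagonal would be statistically invisible and would test
  nothing.

What the generator does *not* emulate: read-level noise and mapping
artifacts, kinetic-signal uncertainty of modification calling, restriction
fragment structure of real Hi-C libraries, copy-number and replication
gradients, plasmids, or correlated placement of motifs with gene starts.
Passing tests therefore demonstrate the correctness and statistical
calibration of the algorithms under the declared generative model, not
robustness to every artifact of real libraries.

## Problem sizes and determinism

The validation suite runs 200 kb genomes and 400-bin matrices with 100
seeds per recovery experiment (400 seeds for the type-I calibration),
sizes chosen so the whole suite completes in minutes on one CPU while
keeping Poisson counting error a small fraction of the planted effects.
All generators are deterministic given the configuration seed; the
reference/test matrix pair shares its uniform draws as described, and each
generator stage uses a fixed offset of the seed so stages can be re-run
independently.

## Known limitations

* The bias statistic's absolute scale depends on the Markov order and on
  the difference-of-log-ratios definition; comparisons across studies
  that use a perpendicular-distance definition need the sqrt(2) rescale.
* The significance model for interactions assumes a single decay law for
  the whole chromosome; strong compartment structure would call for
  distance-and-domain-stratified expectations.
* BH over scan offsets approximates, but is not identical to, FIMO's
  q-value computation.
* Upstream-region extraction treats the chromosome linearly; a gene
  spanning the origin of a circular genome must be annotated in linear
  coordinates.

## A worked run

```{r example}
cfg <- synth_config(seed = 1)
ann <- gen_annotation(cfg)
planted <- plant_methylation(cfg, gen_genome(cfg), ann)
cds <- data.frame(start = ann$genes$start, end = ann$genes$end)
methylation_density(planted$calls, cds)$density_per_kb
methylation_density(planted$calls, intergenic_intervals(ann))$density_per_kb
motif_bias_table(planted$genome$seq, ann, list(cfg$motif))[, c("b", "skew_class")]
```
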