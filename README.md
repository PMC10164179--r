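# methica

Integrative analysis of bacterial N6-methyladenine (6mA) methylomes with
chromosome-conformation (Hi-C) comparison.

DNA adenine methylation is a widespread epigenetic mark in bacteria. In
lactic-acid bacteria such as *Lacticaseibacillus paracasei*, 6mA is laid
down on short degenerate recognition motifs by methyltransferases (for
instance the *pglX* gene of a BREX system), and its genomic placement —
skewed toward coding sequence and toward particular functional categories —
suggests a regulatory role in carbohydrate metabolism. Testing that idea
requires joining several analyses that usually live in separate tools:
motif mapping, composition-controlled occurrence statistics, functional
enrichment, binding-site scanning, and comparative chromosome-conformation
analysis between a methylation-deficient mutant and its wild type.
`methica` implements that pipeline as one tested R package, together with
a synthetic-data generator that plants known signals so every stage can be
validated end to end against ground truth.

## What it computes

* **Motif mapping** — scan degenerate IUPAC motifs (palindromic
  `forward/reverse` pairs supported) on both strands; classify methylation
  calls into the CDS/intergenic partition; densities per kb, per gene, and
  per functional category (COG/KO); motif-table summaries including the
  percent of genomic occurrences that are methylated.
* **Motif usage bias** — expected occurrence counts from class-specific
  Markov composition models (order 0–5, default 2; exact positional DP,
  no motif expansion), and the bias statistic
  `b = log2(O_ig/E_ig) − log2(O_cds/E_cds)` (negative = coding skew).
* **Enrichment statistics** — fold/significance filters for differential
  expression (padj ≤ 0.05, 2.0-fold) and protein (p < 0.05, 1.2-fold)
  tables; two-sided Fisher exact tests per category with
  Benjamini–Hochberg correction; `2^-ddCT` and Pearson helpers for qPCR
  validation.
* **TFBS scanning** — PWMs from binding-site sets; 50–300 bp upstream
  regions that never overlap a CDS; log2-odds scores with *exact*
  p-values from a dynamic program over quantized scores (verified against
  4^w enumeration); BH q-value filtering; overlap of hits with
  methylation calls (methylated vs non-methylated sites).
* **Comparative Hi-C** — binning on a circular chromosome, iterative
  (ICE) balancing, distance-stratified binomial interaction calling
  (p < 0.01, q < 0.01, count > 2), insulation profiles, chromosomal
  interaction domain (CID) calling at insulation minima, and the
  condition-unique interactions / CIDs / insulation regions of a
  two-condition comparison.
* **Synthetic data** — `synth_config()` + `simulate_all()` generate a
  genome, annotation, planted methylated motifs, a differential table
  with a planted enriched category, and a reference/test Hi-C matrix pair
  with planted domains and differential contacts, plus a truth-table
  JSON.

## A worked example

```r
library(methica)

cfg     <- synth_config(seed = 1)          # desk-scale study conditions
ann     <- gen_annotation(cfg)
planted <- plant_methylation(cfg, gen_genome(cfg), ann)

cds <- data.frame(start = ann$genes$start, end = ann$genes$end)
methylation_density(planted$calls, cds)$density_per_kb
#> [1] 1.022955
methylation_density(planted$calls, intergenic_intervals(ann))$density_per_kb
#> [1] 0.6313807

motif_bias_table(planted$genome$seq, ann, list(cfg$motif))[
  , c("motif_id", "O_cds", "E_cds", "O_ig", "E_ig", "b", "skew_class")]
#>      motif_id O_cds    E_cds O_ig     E_ig          b skew_class
#> 1 GCCAT/ATGGC   314 205.9782  210 166.9847 -0.2776001        CDS
```

The planted motif (GCCAT/ATGGC, methylated at ~99% of occurrences,
0.96/0.77 planted occurrences per kb in CDS/intergenic) comes back as a
coding-skewed motif: observed counts exceed the Markov expectation more
strongly in coding sequence (314 vs 206) than in intergenic sequence
(210 vs 167), so `b < 0`. The call densities (1.02 vs 0.63 per kb)
recover the planted contrast within Poisson error.

Comparing the generated Hi-C pair recovers the planted differential
contacts and the domain boundaries:

```r
h  <- gen_hic_pair(cfg)
sr <- call_significant(h$ref,  ice_balance(h$ref)$matrix)
st <- call_significant(h$test, ice_balance(h$test)$matrix)
unique_elements(sr, st)$interactions_unique_b[, c("bin_i", "bin_j", "count", "q")]
#>   bin_i bin_j count            q
#> 1    20    50    64 2.462014e-46
#> 2   100   125    80 2.165326e-58
#> 3   200   215   120 2.663576e-83
#> 4   250   285    23 1.042858e-07
#> 5   350   370    97 4.113038e-70

call_cids(insulation_profile(ice_balance(h$test)$matrix, w = 10))$boundaries
#>   bin strength
#> 1 129 1.487088
#> 2 259 1.509346
#> 3 399 1.695099
```

All five planted 12x contact boosts are unique to the test condition, and
the three detected boundaries sit within one bin of the planted block
edges (130, 260, 0 on the 400-bin circle).

A thin command-line wrapper over the same functions is installed at
`inst/cli/methica.R` (subcommands `simulate`, `map-features`,
`motif-bias`, `enrich`, `hic-compare`).

## Documentation

The methods vignette (`vignettes/methylome-hic-analysis.Rmd`) documents
the statistical models, the tunable parameters and their defaults, what
the synthetic generator does and does not emulate, numerical choices, and
known limitations.
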