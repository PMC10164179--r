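Package: methica
Title: Bacterial 6mA Methylome Analysis with Chromosome Conformation Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of N6-methyladenine (6mA)
    methylomes in bacteria. Maps degenerate (IUPAC) methylation motifs onto a
    genome, partitions methylated sites between coding and intergenic
    sequence, computes Markov-model expected motif frequencies and
    coding/intergenic usage-bias statistics, summarises methylation density
    per functional category (COG/KO), performs Fisher/Benjamini-Hochberg
    functional enrichment of differential-expression tables, scans upstream
    regions with position weight matrices using exact dynamic-programming
    p-values and intersects hits with methylation calls, and compares Hi-C
    contact maps between two conditions (iterative balancing, distance-decay
    significant-interaction calling, insulation profiles, chromosomal
    interaction domains, and condition-unique elements). A synthetic-data
    generator plants known motif, enrichment, domain and differential-contact
    signals so that every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
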