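#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Classify methylation calls into CDS vs intergenic
#'
#' A site is CDS if and only if its position lies inside at least one gene
#' interval, regardless of gene strand; otherwise it is intergenic. The
#' classification is an exact partition: every call is counted once at class
#' level even where genes overlap, while `per_gene` counts a site once per
#' overlapping gene.
#'
#' @param calls data.frame of methylation calls (`position` 0-based,
#'   `strand`).
#' @param annotation A `genome_annotation`.
#' @return List with `n_cds`, `n_ig` and `per_gene` (named integer vector of
#'   per-gene site counts; genes without sites have count 0).
#' @export
classify_sites <- function(calls, annotation) {
  pos <- calls$position
  if (length(pos) > 0 &&
      (any(pos < 0) || any(pos >= annotation$genome_length))) {
    stop("methylation call position outside [0, genome_length)")
  }
  g <- annotation$genes
  per_gene <- stats::setNames(integer(nrow(g)), g$gene_id)
  if (length(pos) == 0L) {
    return(list(n_cds = 0L, n_ig = 0L, per_gene = per_gene))
  }
  if (nrow(g) == 0L) {
    return(list(n_cds = 0L, n_ig = length(pos), per_gene = per_gene))
  }
  # half-open [start, end) in 0-based == closed [start+1, end] in 1-based
  q <- IRanges(start = pos + 1L, width = 1L)
  s <- IRanges(start = g$start + 1L, end = g$end)
  ov <- findOverlaps(q, s)
  in_cds <- unique(queryHits(ov))
  tab <- table(factor(subjectHits(ov), levels = seq_len(nrow(g))))
  per_gene[] <- as.integer(tab)
  list(n_cds = length(in_cds),
       n_ig = length(pos) - length(in_cds),
       per_gene = per_gene)
}

#' Methylation density of a set of intervals
#'
#' @param calls data.frame of methylation calls.
#' @param intervals data.frame with `start`, `end` (0-based half-open),
#'   non-overlapping.
#' @return List with `site_count`, `length_bp` and `density_per_kb`
#'   (`1000 * site_count / length_bp`).
#' @export
methylation_density <- function(calls, intervals) {
  len <- sum(intervals$end - intervals$start)
  if (len <= 0) stop("total interval length must be > 0")
  if (nrow(intervals) > 1L) {
    o <- order(intervals$start)
    if (any(intervals$start[o][-1] < intervals$end[o][-nrow(intervals)])) {
      stop("intervals must be non-overlapping")
    }
  }
  n <- 0L
  if (nrow(calls) > 0L) {
    q <- IRanges(start = calls$position + 1L, width = 1L)
    s <- IRanges(start = intervals$start + 1L, end = intervals$end)
    n <- length(unique(queryHits(findOverlaps(q, s))))
  }
  list(site_count = n, length_bp = len, density_per_kb = 1000 * n / len)
}

#' Intergenic complement of an annotation
#'
#' @param annotation A `genome_annotation`.
#' @return data.frame of intergenic intervals (`start`, `end`), the
#'   complement of the union of gene intervals on the linear chromosome.
#' @export
intergenic_intervals <- function(annotation) {
  g <- annotation$genes
  L <- annotation$genome_length
  if (nrow(g) == 0L) return(data.frame(start = 0L, end = L))
  ir <- IRanges::reduce(IRanges(start = g$start + 1L, end = g$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = L)
  data.frame(start = BiocGenerics::start(gaps) - 1L,
             end = BiocGenerics::end(gaps))
}

#' Per-gene methylation density grouped by functional category
#'
#' Each gene is assigned to its KO or COG group; group summaries report the
#' median per-gene density so that categories can be ranked by median
#' methylation density. Genes lacking the chosen tag are skipped and their
#' number reported.
#'
#' @param calls data.frame of methylation calls.
#' @param annotation A `genome_annotation` with `cog`/`ko` tags.
#' @param key `"ko"` or `"cog"`.
#' @return List with `genes` (per-gene density rows: `gene_id`, `category`,
#'   `site_count`, `length_bp`, `density_per_kb`), `groups` (per-category
#'   `median_density`, `n_genes`, sorted by decreasing median) and
#'   `n_untagged`.
#' @export
density_by_category <- function(calls, annotation, key = c("ko", "cog")) {
  key <- match.arg(key)
  g <- annotation$genes
  tag <- g[[key]]
  keep <- !is.na(tag) & nzchar(tag)
  if (!any(keep)) stop("no gene carries a '", key, "' tag")
  cls <- classify_sites(calls, annotation)
  genes <- data.frame(
    gene_id = g$gene_id[keep],
    category = tag[keep],
    site_count = as.integer(cls$per_gene[g$gene_id[keep]]),
    length_bp = (g$end - g$start)[keep],
    stringsAsFactors = FALSE
  )
  genes$density_per_kb <- 1000 * genes$site_count / genes$length_bp
  med <- tapply(genes$density_per_kb, genes$category, stats::median)
  groups <- data.frame(category = names(med),
                       median_density = as.numeric(med),
                       n_genes = as.integer(table(genes$category)[names(med)]),
                       stringsAsFactors = FALSE)
  groups <- groups[order(-groups$median_density, groups$category), ,
                   drop = FALSE]
  rownames(groups) <- NULL
  list(genes = genes, groups = groups, n_untagged = sum(!keep))
}

#' Proportion of methylated motifs
#'
#' The percentage of genomic motif occurrences detected as methylated,
#' reported to two decimals as in published motif tables.
#'
#' @param n_methylated Number of methylated motif occurrences.
#' @param n_total Total genomic occurrences of the motif.
#' @param digits Rounding for table display (default 2).
#' @return Percentage, `100 * n_methylated / n_total`, rounded.
#' @examples
#' motif_methylation_summary(1636, 1652)  # 99.03
#' @export
motif_methylation_summary <- function(n_methylated, n_total, digits = 2) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  if (any(n_methylated < 0) || any(n_methylated > n_total)) {
    stop("need 0 <= n_methylated <= n_total")
  }
  round(100 * n_methylated / n_total, digits)
}

#' Motif-table summary from a motifs.csv
#'
#' Builds a motif-table style summary (motif, detected and genomic
#' occurrence counts, percent methylated) from `motifs_csv` rows.
#'
#' @param rows Output of `read_methylation(..., dialect = "motifs_csv")`.
#' @return data.frame with `motif`, `n_detected`, `n_genome`,
#'   `pct_methylated`.
#' @export
summarize_motifs_csv <- function(rows) {
  data.frame(
    motif = rows$motifString,
    n_detected = rows$nDetected,
    n_genome = rows$nGenome,
    pct_methylated = motif_methylation_summary(rows$nDetected, rows$nGenome),
    stringsAsFactors = FALSE
  )
}
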