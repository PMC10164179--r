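#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom utils read.csv read.delim write.csv write.table
NULL

# All internal coordinates are 0-based half-open; conversion to and from the
# 1-based inclusive conventions of GFF3 happens only in this file.

#' Read a FASTA file into sequence records
#'
#' Strict dialect: sequences are upper-cased and must contain only
#' `A,C,G,T,N`; internal whitespace or other characters are format errors.
#'
#' @param path FASTA file.
#' @return A data.frame with columns `id` and `seq` (upper-case), one row per
#'   record, in file order.
#' @export
read_fasta <- function(path) {
  raw <- readLines(path)
  seq_lines <- which(!grepl("^>", raw) & nzchar(raw))
  bad_line <- seq_lines[grepl("[^ACGTNacgtn]", raw[seq_lines])]
  if (length(bad_line) > 0L) {
    stop("FASTA format error in '", path, "' line ", bad_line[1],
         ": characters outside {A,C,G,T,N}")
  }
  set <- tryCatch(readDNAStringSet(path),
                  error = function(e) stop("FASTA format error in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA record '", names(set)[bad][1],
         "' contains characters outside {A,C,G,T,N}")
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with `id`, `seq` columns (as from [read_fasta()]).
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- DNAStringSet(records$seq)
  names(set) <- records$id
  writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a genome annotation
#'
#' @param genome_length Chromosome length in bp.
#' @param genes data.frame with columns `gene_id`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`/`.`), and optional `cog` (single COG
#'   letter) and `ko` (KEGG Orthology id) columns. Rows are sorted by start.
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(genome_length, genes) {
  stopifnot(genome_length > 0)
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        cog = character(0), ko = character(0),
                        stringsAsFactors = FALSE)
  } else {
    if (!all(c("gene_id", "start", "end", "strand") %in% names(genes))) {
      stop("genes must have gene_id, start, end, strand columns")
    }
    if (is.null(genes$cog)) genes$cog <- NA_character_
    if (is.null(genes$ko)) genes$ko <- NA_character_
    if (any(genes$start < 0) || any(genes$end > genome_length)) {
      stop("gene interval outside [0, genome_length)")
    }
    if (any(genes$end <= genes$start)) stop("gene with end <= start")
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(genome_length = as.integer(genome_length), genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", nrow(x$genes), " genes on ",
      x$genome_length, " bp\n", sep = "")
  invisible(x)
}

#' Read a GFF3 gene annotation
#'
#' Keeps CDS features, converts 1-based inclusive GFF3 coordinates to the
#' package's internal 0-based half-open convention, and picks up optional
#' `cog=<letter>` and `ko=<Kxxxxx>` attributes. Features beyond
#' `genome_length` or with end < start are format errors.
#'
#' @param path GFF3 file.
#' @param genome_length Chromosome length in bp.
#' @return A `genome_annotation`.
#' @export
read_gff3 <- function(path, genome_length) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 format error in '", path,
                                          "': ", conditionMessage(e)))
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) {
    return(genome_annotation(genome_length, NULL))
  }
  start1 <- BiocGenerics::start(gr)   # 1-based inclusive
  end1 <- BiocGenerics::end(gr)
  if (any(end1 < start1)) stop("GFF3 format error: end < start")
  if (any(start1 < 1) || any(end1 > genome_length)) {
    stop("GFF3 coordinates outside [1, genome_length]")
  }
  mc <- mcols(gr)
  pick <- function(cols) {
    for (cl in cols) if (cl %in% names(mc)) return(as.character(mc[[cl]]))
    rep(NA_character_, length(gr))
  }
  ids <- pick(c("ID", "Name", "gene_id", "locus_tag"))
  if (anyNA(ids)) ids[is.na(ids)] <- paste0("gene_", which(is.na(ids)))
  genes <- data.frame(
    gene_id = ids,
    start = start1 - 1L,               # to 0-based half-open
    end = end1,
    strand = as.character(BiocGenerics::strand(gr)),
    cog = pick("cog"),
    ko = pick("ko"),
    stringsAsFactors = FALSE
  )
  genes$strand[genes$strand == "*"] <- "."
  genome_annotation(genome_length, genes)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open intervals are written
#' back as 1-based inclusive GFF3 CDS rows with `cog`/`ko` attributes.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output file.
#' @param seqname Sequence name for column 1.
#' @export
write_gff3 <- function(annotation, path, seqname = "chr") {
  g <- annotation$genes
  if (nrow(g) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- g$strand
  strand[strand == "."] <- "*"
  gr <- GRanges(seqnames = seqname,
                ranges = IRanges(start = g$start + 1L, end = g$end),
                strand = strand)
  mcols(gr)$type <- "CDS"
  mcols(gr)$phase <- 0L
  mcols(gr)$ID <- g$gene_id
  if (!all(is.na(g$cog))) mcols(gr)$cog <- g$cog
  if (!all(is.na(g$ko))) mcols(gr)$ko <- g$ko
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read methylation calls or motif summaries
#'
#' Two dialects are supported, emulating the text outputs of SMRT-style base
#' modification analysis:
#' \describe{
#'   \item{`mods_gff`}{GFF3-like rows of single-base `m6A` features; the
#'     1-based position is converted to a 0-based `position`.}
#'   \item{`motifs_csv`}{CSV with header
#'     `motifString,centerPos,fraction,nDetected,nGenome`, returned verbatim
#'     for summary reporting.}
#' }
#'
#' @param path Input file.
#' @param dialect `"mods_gff"` or `"motifs_csv"`.
#' @return For `mods_gff`, a data.frame of methylation calls with columns
#'   `position` (0-based), `strand`, `motif_id`, `score`; for `motifs_csv`,
#'   the summary rows.
#' @export
read_methylation <- function(path, dialect = c("mods_gff", "motifs_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "motifs_csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("motifString", "centerPos", "fraction", "nDetected", "nGenome")
    if (!all(need %in% names(df))) {
      stop("motifs_csv must have columns ", paste(need, collapse = ","))
    }
    return(df[, need])
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(position = integer(0), strand = character(0),
                      motif_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 8L)) {
    stop("mods_gff format error: line with fewer than 8 columns")
  }
  start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(start1) || anyNA(end1)) {
    stop("mods_gff format error: non-integer coordinate")
  }
  if (any(start1 != end1)) stop("mods_gff: m6A calls must be single-base")
  strand <- vapply(fields, `[[`, "", 7L)
  if (!all(strand %in% c("+", "-"))) stop("mods_gff: strand must be + or -")
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  attrs <- vapply(fields, function(f) if (length(f) >= 9L) f[[9L]] else "", "")
  motif_id <- ifelse(grepl("motif=", attrs),
                     sub(".*motif=([^;]*).*", "\\1", attrs), NA_character_)
  data.frame(position = start1 - 1L, strand = strand, motif_id = motif_id,
             score = score, stringsAsFactors = FALSE)
}

#' Write methylation calls as a mods GFF
#'
#' @param calls data.frame with `position` (0-based), `strand`, optional
#'   `motif_id`, `score`.
#' @param path Output file.
#' @param seqname Sequence name.
#' @export
write_methylation <- function(calls, path, seqname = "chr") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(calls) > 0L) {
    score <- if (is.null(calls$score)) rep(30, nrow(calls)) else calls$score
    score[is.na(score)] <- 30
    attrs <- if (is.null(calls$motif_id)) {
      rep(".", nrow(calls))
    } else {
      ifelse(is.na(calls$motif_id), ".", paste0("motif=", calls$motif_id))
    }
    writeLines(paste(seqname, "methica", "m6A",
                     calls$position + 1L, calls$position + 1L,
                     score, calls$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

#' Write a motifs.csv summary table
#'
#' @param rows data.frame with columns
#'   `motifString,centerPos,fraction,nDetected,nGenome`.
#' @param path Output file.
#' @export
write_motifs_csv <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bin-pair contact table
#'
#' TSV with integer columns `bin_i`, `bin_j`, `count`. Pairs are
#' canonicalized to `bin_i <= bin_j` and duplicate pairs are summed.
#'
#' @param path TSV file (header optional; detected).
#' @return data.frame with `bin_i`, `bin_j`, `count`, sorted by pair.
#' @export
read_contacts <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("bin", first, ignore.case = TRUE)
  df <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("contact table needs 3 columns (bin_i, bin_j, count)")
  df <- df[, 1:3]
  names(df) <- c("bin_i", "bin_j", "count")
  if (!all(vapply(df, is.numeric, TRUE)) ||
      any(df != floor(df))) {
    stop("contact table entries must be integers")
  }
  if (any(df$count < 0)) stop("negative contact count")
  i <- pmin(df$bin_i, df$bin_j)
  j <- pmax(df$bin_i, df$bin_j)
  agg <- stats::aggregate(list(count = df$count),
                          by = list(bin_i = i, bin_j = j), FUN = sum)
  agg <- agg[order(agg$bin_i, agg$bin_j), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write a bin-pair contact table
#'
#' @param pairs data.frame with `bin_i`, `bin_j`, `count`.
#' @param path Output TSV.
#' @export
write_contacts <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write bin regions as BED
#'
#' Regions given in bin units are written in bp (`start = bin * bin_size`),
#' BED being already 0-based half-open. A region that wraps past the end of
#' the circular chromosome is split into two BED lines with the same name.
#'
#' @param regions data.frame with `start_bin`, `end_bin` (half-open, may wrap
#'   with `end_bin <= start_bin`), optional `name`.
#' @param path Output BED.
#' @param bin_size Bin width in bp.
#' @param n_bins Total bins (needed to resolve wrapped regions).
#' @param seqname Chromosome name.
#' @export
write_bed_regions <- function(regions, path, bin_size, n_bins,
                              seqname = "chr") {
  lines <- character(0)
  nm <- if (is.null(regions$name)) paste0("region_", seq_len(nrow(regions)))
        else regions$name
  for (k in seq_len(nrow(regions))) {
    s <- regions$start_bin[k]; e <- regions$end_bin[k]
    if (e > s) {
      lines <- c(lines, paste(seqname, s * bin_size, e * bin_size, nm[k],
                              sep = "\t"))
    } else {  # wraps origin
      lines <- c(lines,
                 paste(seqname, s * bin_size, n_bins * bin_size, nm[k],
                       sep = "\t"),
                 paste(seqname, 0L, e * bin_size, nm[k], sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
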