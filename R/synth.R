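#' @importFrom stats rpois rbinom runif qpois
NULL

# The paper's top-10 carbohydrate-metabolism KO groups; used as the default
# KO palette so synthetic per-KO density tables look like real ones.
.KO_PALETTE <- c("K02795", "K01223", "K01182", "K03332", "K01624",
                 "K02800", "K00158", "K02770", "K02761", "K02775")
.COG_PALETTE <- c("C", "D", "E", "F", "G", "H", "I", "J", "K", "L", "M",
                  "O", "P", "S", "T", "U", "V")

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the emulated study system: a circular bacterial
#' chromosome at desk scale (200 kb standing in for ~3 Mb), ~50% coding,
#' a palindromic 6mA motif (GCCAT/ATGGC) planted at densities whose called
#' sites emulate the published coding vs intergenic methylation densities
#' (0.95 vs 0.76 per kb at a ~99% per-site call rate), a differential table
#' with the carbohydrate COG category planted at elevated odds, and a
#' 400-bin circular contact map with power-law distance decay, three
#' planted interaction domains, and planted differential contacts.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param genome_length Chromosome length (bp).
#' @param markov_order Order of the composition model (0-5).
#' @param base_probs Base probabilities (A,C,G,T) for order 0 (and the
#'   stationary start of higher orders).
#' @param transition_probs Optional 4^order x 4 transition matrix.
#' @param n_genes,gene_length_range Gene count and length range (bp).
#' @param cog_palette,ko_palette Category palettes for gene tags.
#' @param ko_tag_fraction Fraction of genes given a KO tag.
#' @param motif The planted `iupac_motif` (needs `methylated_offset`).
#' @param rate_cds,rate_ig Planted motif densities (occurrences per kb) in
#'   coding/intergenic sequence.
#' @param meth_fraction Probability a planted occurrence is called
#'   methylated.
#' @param hic_bins Number of Hi-C bins (>= 20).
#' @param bin_size Hi-C bin width (bp).
#' @param decay_exponent Power-law distance-decay exponent alpha (> 0).
#' @param hic_scale Expected count at unit distance.
#' @param cid_blocks data.frame (`start_bin`, `end_bin`, `within_boost`) of
#'   planted self-associating domains (reference condition).
#' @param cid_blocks_test Blocks for the test condition (default: same).
#' @param diff_contacts data.frame (`bin_i`, `bin_j`, `boost`) of planted
#'   test-specific contact boosts.
#' @param de_frac Baseline probability a gene is differential.
#' @param enriched_category COG letter planted at elevated odds.
#' @param enrichment_odds Odds multiplier for the planted category.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         genome_length = 200000L,
                         markov_order = 0L,
                         base_probs = c(A = 0.27, C = 0.23, G = 0.23,
                                        T = 0.27),
                         transition_probs = NULL,
                         n_genes = 100L,
                         gene_length_range = c(500L, 1500L),
                         cog_palette = .COG_PALETTE,
                         ko_palette = .KO_PALETTE,
                         ko_tag_fraction = 0.7,
                         motif = iupac_motif("GCCAT", "ATGGC",
                                             methylated_offset = 3,
                                             id = "GCCAT/ATGGC"),
                         rate_cds = 0.96,
                         rate_ig = 0.77,
                         meth_fraction = 0.99,
                         hic_bins = 400L,
                         bin_size = 1000L,
                         decay_exponent = 1,
                         hic_scale = 50,
                         cid_blocks = data.frame(
                           start_bin = c(0L, 130L, 260L),
                           end_bin = c(130L, 260L, 400L),
                           within_boost = 3),
                         cid_blocks_test = NULL,
                         diff_contacts = data.frame(
                           bin_i = c(20L, 100L, 200L, 250L, 350L),
                           bin_j = c(50L, 125L, 215L, 285L, 370L),
                           boost = 12),
                         de_frac = 0.045,
                         enriched_category = "G",
                         enrichment_odds = 8) {
  stopifnot(genome_length > 0, n_genes >= 0,
            rate_cds >= 0, rate_ig >= 0,
            meth_fraction >= 0, meth_fraction <= 1,
            de_frac >= 0, de_frac <= 1, enrichment_odds > 0,
            abs(sum(base_probs) - 1) < 1e-6)
  if (markov_order > 5) stop("Markov order > 5 is unsupported")
  if (decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (hic_bins < 20) stop("need hic_bins >= 20")
  if (!is.null(cid_blocks) && nrow(cid_blocks) > 0 &&
      (any(cid_blocks$start_bin < 0) || any(cid_blocks$end_bin > hic_bins))) {
    stop("cid_blocks must lie within [0, hic_bins]")
  }
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              markov_order = as.integer(markov_order),
              base_probs = base_probs, transition_probs = transition_probs,
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              cog_palette = cog_palette, ko_palette = ko_palette,
              ko_tag_fraction = ko_tag_fraction,
              motif = motif, rate_cds = rate_cds, rate_ig = rate_ig,
              meth_fraction = meth_fraction,
              hic_bins = as.integer(hic_bins),
              bin_size = as.integer(bin_size),
              decay_exponent = decay_exponent, hic_scale = hic_scale,
              cid_blocks = cid_blocks,
              cid_blocks_test = if (is.null(cid_blocks_test)) cid_blocks
                                else cid_blocks_test,
              diff_contacts = diff_contacts,
              de_frac = de_frac, enriched_category = enriched_category,
              enrichment_odds = enrichment_odds)
  structure(cfg, class = "synth_config")
}

#' Generate a random genome sequence
#'
#' Markov base composition of the configured order; deterministic given the
#' config seed.
#'
#' @param config A `synth_config`.
#' @return A one-row data.frame (`id`, `seq`), as from [read_fasta()].
#' @export
gen_genome <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  m <- config$markov_order
  p <- config$base_probs
  if (m == 0L || is.null(config$transition_probs)) {
    # i.i.d. draw (an order-m chain with identical rows reduces to this)
    seq <- paste(sample(.BASES, L, replace = TRUE, prob = p), collapse = "")
  } else {
    trans <- config$transition_probs
    stopifnot(nrow(trans) == 4^m, ncol(trans) == 4)
    bases <- integer(L)
    bases[1:m] <- sample(1:4, m, replace = TRUE, prob = p)
    state <- 0L
    for (i in 1:m) state <- state * 4L + (bases[i] - 1L)
    mod <- 4L^(m - 1L)
    for (i in (m + 1L):L) {
      b <- sample.int(4L, 1L, prob = trans[state + 1L, ])
      bases[i] <- b
      state <- (state %% mod) * 4L + (b - 1L)
    }
    seq <- paste(.BASES[bases], collapse = "")
  }
  data.frame(id = paste0("synthetic_chr_seed", config$seed), seq = seq,
             stringsAsFactors = FALSE)
}

#' Generate a gene annotation
#'
#' Non-overlapping CDS intervals with alternating strands, uniform-random
#' gaps, and category tags drawn from the configured palettes.
#'
#' @param config A `synth_config`.
#' @return A `genome_annotation`.
#' @export
gen_annotation <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_genes
  L <- config$genome_length
  if (n == 0L) return(genome_annotation(L, NULL))
  lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                 n, replace = TRUE)
  slack <- L - sum(lens)
  if (slack < n + 1L) stop("infeasible packing: genes do not fit the genome")
  # uniform-random gaps by a broken-stick over the slack
  cuts <- sort(runif(n))
  gaps <- floor(diff(c(0, cuts, 1)) * slack)
  starts <- cumsum(gaps[-(n + 1L)] + c(0, lens[-n]))
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n)),
    start = as.integer(starts),
    end = as.integer(starts + lens),
    strand = rep_len(c("+", "-"), n),
    cog = sample(config$cog_palette, n, replace = TRUE),
    ko = ifelse(runif(n) < config$ko_tag_fraction,
                sample(config$ko_palette, n, replace = TRUE),
                NA_character_),
    stringsAsFactors = FALSE
  )
  genome_annotation(L, genes)
}

# sample a concrete realization of an IUPAC motif
.realize_motif <- function(allowed) {
  paste(.BASES[vapply(allowed, function(a) a[sample.int(length(a), 1L)],
                      0L) + 1L], collapse = "")
}

#' Plant methylated motif occurrences into a genome
#'
#' Motif instances are written into the sequence at Poisson-sampled
#' positions with per-class densities `rate_cds` and `rate_ig` (occurrences
#' per kb; overlapping draws are re-drawn), on a uniformly random strand;
#' each instance is emitted as a methylation call at its motif adenine with
#' probability `meth_fraction`. The truth table records every planted
#' instance.
#'
#' @param config A `synth_config`.
#' @param genome Output of [gen_genome()] (one-row data.frame).
#' @param annotation A `genome_annotation`.
#' @return List with `genome` (sequence with motifs written in), `calls`
#'   (methylation-call data.frame) and `truth` (planted instances:
#'   `start`, `end`, `strand`, `class`, `methylated`, `call_position`).
#' @export
plant_methylation <- function(config, genome, annotation) {
  set.seed(config$seed + 2L)
  motif <- config$motif
  if (is.null(motif$methylated_offset)) {
    stop("the planted motif needs a methylated_offset")
  }
  k <- nchar(motif$forward)
  allowed <- .allowed_idx(motif$forward)
  chars <- strsplit(genome$seq, "")[[1]]
  g <- annotation$genes
  classes <- list(
    CDS = data.frame(start = g$start, end = g$end),
    IG = intergenic_intervals(annotation)
  )
  rates <- c(CDS = config$rate_cds, IG = config$rate_ig)
  truth <- list()
  occupied_start <- integer(0)
  for (cls in names(classes)) {
    iv <- classes[[cls]]
    iv <- iv[iv$end - iv$start >= k, , drop = FALSE]
    if (nrow(iv) == 0L) next
    n_slots <- iv$end - iv$start - k + 1L
    total_kb <- sum(iv$end - iv$start) / 1000
    n_inst <- rpois(1L, rates[[cls]] * total_kb)
    if (n_inst == 0L) next
    placed <- 0L
    tries <- 0L
    budget <- 50L * n_inst + 200L
    while (placed < n_inst) {
      tries <- tries + 1L
      if (tries > budget) {
        stop("could not place requested motif density without overlaps")
      }
      w <- sample.int(nrow(iv), 1L, prob = n_slots)
      s <- iv$start[w] + sample.int(n_slots[w], 1L) - 1L
      if (any(abs(occupied_start - s) < k)) next
      word <- .realize_motif(allowed)
      strand <- if (runif(1) < 0.5) "+" else "-"
      written <- if (strand == "+") word else
        as.character(Biostrings::reverseComplement(DNAString(word)))
      chars[(s + 1L):(s + k)] <- strsplit(written, "")[[1]]
      occupied_start <- c(occupied_start, s)
      methylated <- runif(1) < config$meth_fraction
      call_pos <- if (strand == "+") s + motif$methylated_offset else
        s + (k - 1L) - motif$methylated_offset
      truth[[length(truth) + 1L]] <- data.frame(
        start = s, end = s + k, strand = strand, class = cls,
        methylated = methylated, call_position = call_pos,
        stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(start = integer(0), end = integer(0), strand = character(0),
               class = character(0), methylated = logical(0),
               call_position = integer(0), stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  meth <- truth[truth$methylated, , drop = FALSE]
  calls <- data.frame(position = meth$call_position, strand = meth$strand,
                      motif_id = rep(motif$id, nrow(meth)),
                      score = rep(40, nrow(meth)), stringsAsFactors = FALSE)
  genome$seq <- paste(chars, collapse = "")
  list(genome = genome, calls = calls, truth = truth)
}

#' Generate a reference/test pair of Hi-C contact matrices
#'
#' Expected counts follow a circular power-law decay
#' `mu(i,j) = C * d(i,j)^-alpha` (distance floored at 1 bin), multiplied by
#' `within_boost` for pairs inside a planted block, and in the test matrix
#' additionally by the planted differential boosts. Counts are Poisson via
#' the quantile transform of one shared uniform draw per pair, so the two
#' matrices are identical wherever their expected counts coincide.
#'
#' @param config A `synth_config`.
#' @return List with `ref`, `test` (raw `contact_matrix` objects) and
#'   `truth` (`boundaries_ref`, `boundaries_test` as 0-based bins, and
#'   `diff_contacts`).
#' @export
gen_hic_pair <- function(config) {
  set.seed(config$seed + 3L)
  n <- config$hic_bins
  alpha <- config$decay_exponent
  idx <- 0:(n - 1L)
  d <- outer(idx, idx, function(i, j) bin_distance(i, j, n))
  mu0 <- config$hic_scale * pmax(d, 1)^(-alpha)
  block_mask <- function(blocks) {
    m <- matrix(1, n, n)
    if (!is.null(blocks) && nrow(blocks) > 0) {
      for (b in seq_len(nrow(blocks))) {
        bins <- .cid_bins(blocks$start_bin[b], blocks$end_bin[b], n) + 1L
        m[bins, bins] <- m[bins, bins] * blocks$within_boost[b]
      }
    }
    m
  }
  mu_ref <- mu0 * block_mask(config$cid_blocks)
  mu_test <- mu0 * block_mask(config$cid_blocks_test)
  dc <- config$diff_contacts
  if (!is.null(dc) && nrow(dc) > 0) {
    for (r in seq_len(nrow(dc))) {
      i <- dc$bin_i[r] + 1L; j <- dc$bin_j[r] + 1L
      mu_test[i, j] <- mu_test[i, j] * dc$boost[r]
      mu_test[j, i] <- mu_test[i, j]
    }
  }
  u <- matrix(0, n, n)
  ut <- upper.tri(u, diag = TRUE)
  u[ut] <- runif(sum(ut))
  draw <- function(mu) {
    M <- matrix(0, n, n)
    M[ut] <- qpois(u[ut], mu[ut])
    M <- M + t(M) - diag(diag(M))
    M
  }
  edges <- function(blocks) {
    if (is.null(blocks) || nrow(blocks) == 0) return(integer(0))
    sort(unique(c(blocks$start_bin, blocks$end_bin %% n)))
  }
  list(
    ref = contact_matrix(draw(mu_ref), bin_size = config$bin_size),
    test = contact_matrix(draw(mu_test), bin_size = config$bin_size),
    truth = list(boundaries_ref = edges(config$cid_blocks),
                 boundaries_test = edges(config$cid_blocks_test),
                 diff_contacts = dc)
  )
}

#' Generate a differential-expression table with a planted enriched category
#'
#' Each gene is flagged differential with probability `de_frac`, with the
#' odds multiplied by `enrichment_odds` for genes in `enriched_category`.
#' `log2fc`, `p` and `padj` are back-filled consistently with the flags
#' (|log2fc| >= 1 and padj <= 0.05 iff differential).
#'
#' @param config A `synth_config`.
#' @param annotation A `genome_annotation` (COG tags used).
#' @return List with `table` (data.frame `id`, `log2fc`, `p`, `padj`) and
#'   `truth` (`de_ids`, `enriched_category`).
#' @export
gen_de_table <- function(config, annotation) {
  set.seed(config$seed + 4L)
  g <- annotation$genes
  if (nrow(g) == 0L) stop("annotation has no genes")
  if (!config$enriched_category %in% config$cog_palette) {
    stop("enriched_category must be in the COG palette")
  }
  odds0 <- config$de_frac / (1 - config$de_frac)
  odds1 <- odds0 * config$enrichment_odds
  p_in <- odds1 / (1 + odds1)
  prob <- ifelse(!is.na(g$cog) & g$cog == config$enriched_category,
                 p_in, config$de_frac)
  de <- runif(nrow(g)) < prob
  n <- nrow(g)
  # mostly upregulated, as is typical when a repressive mark is lost
  sign <- ifelse(runif(n) < 0.85, 1, -1)
  log2fc <- ifelse(de, sign * runif(n, 1, 4), runif(n, -0.9, 0.9))
  padj <- ifelse(de, runif(n, 1e-6, 0.05), runif(n, 0.06, 1))
  p <- padj * runif(n, 0.2, 1)
  list(table = data.frame(id = g$gene_id, log2fc = log2fc, p = p,
                          padj = padj, stringsAsFactors = FALSE),
       truth = list(de_ids = g$gene_id[de],
                    enriched_category = config$enriched_category))
}

#' Generate and write a full synthetic data set
#'
#' Runs every generator and writes the standard files plus a truth-table
#' JSON to `outdir`.
#'
#' @param config A `synth_config`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with all generated objects and file paths.
#' @export
simulate_all <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome0 <- gen_genome(config)
  annotation <- gen_annotation(config)
  planted <- plant_methylation(config, genome0, annotation)
  hic <- gen_hic_pair(config)
  de <- gen_de_table(config, annotation)

  paths <- list(
    fasta = file.path(outdir, "genome.fasta"),
    gff = file.path(outdir, "genes.gff3"),
    mods = file.path(outdir, "modifications.gff"),
    motifs = file.path(outdir, "motifs.csv"),
    de = file.path(outdir, "de_table.tsv"),
    ref_contacts = file.path(outdir, "contacts_ref.tsv"),
    test_contacts = file.path(outdir, "contacts_test.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_fasta(planted$genome, paths$fasta)
  write_gff3(annotation, paths$gff, seqname = genome0$id)
  write_methylation(planted$calls, paths$mods, seqname = genome0$id)
  n_genome <- count_motif_dyads(
    find_motif_occurrences(planted$genome$seq, config$motif))
  write_motifs_csv(data.frame(
    motifString = config$motif$forward,
    centerPos = config$motif$methylated_offset,
    fraction = if (n_genome > 0) nrow(planted$calls) / n_genome else 0,
    nDetected = nrow(planted$calls),
    nGenome = n_genome), paths$motifs)
  write.table(de$table, paths$de, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write_contacts(contacts_to_pairs(hic$ref), paths$ref_contacts)
  write_contacts(contacts_to_pairs(hic$test), paths$test_contacts)
  truth <- list(planted_motifs = planted$truth,
                hic = hic$truth, de = de$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(config = config, genome = planted$genome,
                 annotation = annotation, calls = planted$calls,
                 hic = hic, de = de, truth = truth, paths = paths))
}
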