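#' @importFrom Biostrings oligonucleotideFrequency
NULL

.BASES <- c("A", "C", "G", "T")

#' Train a Markov composition model
#'
#' Maximum-likelihood transition probabilities of DNA base composition with
#' additive pseudocounts; the initial distribution is the empirical m-mer
#' frequency. Windows containing `N` are ignored in counting.
#'
#' @param seqs Character vector of training sequences (fragments are counted
#'   separately; no artificial junctions are introduced).
#' @param order Model order m (0 to 5).
#' @param pseudocount Additive pseudocount on transition and initial counts.
#' @return A `markov_model` with fields `order`, `init` (probabilities over
#'   the 4^m m-mers in lexicographic order), `trans` (4^m x 4 matrix of
#'   P(base | preceding m-mer); for m = 0 a single row) and `pseudocount`.
#' @examples
#' m <- train_markov("AAAT", order = 0, pseudocount = 0)
#' m$trans  # P(A) = 0.75, P(T) = 0.25
#' @export
train_markov <- function(seqs, order = 2, pseudocount = 1) {
  if (order < 0) stop("order must be >= 0")
  if (order > 5) stop("orders above 5 are not supported")
  set <- DNAStringSet(toupper(seqs))
  k <- order + 1L
  counts_k <- colSums(oligonucleotideFrequency(set, width = k))
  # lexicographic order: last character varies fastest, so rows (contexts)
  # come out in lexicographic m-mer order
  trans_counts <- matrix(counts_k, ncol = 4L, byrow = TRUE)
  ctx_names <- if (order == 0L) "" else
    names(colSums(oligonucleotideFrequency(set, width = order)))
  rownames(trans_counts) <- ctx_names
  colnames(trans_counts) <- .BASES
  trans <- (trans_counts + pseudocount) /
    (rowSums(trans_counts) + 4 * pseudocount)
  if (order == 0L) {
    init <- stats::setNames(1, "")
  } else {
    counts_m <- colSums(oligonucleotideFrequency(set, width = order))
    init <- (counts_m + pseudocount) / (sum(counts_m) +
                                          4^order * pseudocount)
  }
  structure(list(order = as.integer(order), init = init, trans = trans,
                 pseudocount = pseudocount),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat("<markov_model> order ", x$order, ", pseudocount ", x$pseudocount,
      "\n", sep = "")
  invisible(x)
}

# allowed base indices (0-3) per motif position
.allowed_idx <- function(motif_string) {
  lapply(strsplit(.check_iupac(motif_string), "")[[1]], function(ch) {
    match(strsplit(IUPAC_CODE_MAP[[ch]], "")[[1]], .BASES) - 1L
  })
}

#' Probability that the model emits a word matching a degenerate motif
#'
#' Computed without expanding the motif: for order 0 as the product of
#' per-position marginals, for order >= 1 by a positional dynamic program
#' over the 4^m context states, so `N`-runs cost nothing extra.
#'
#' @param model A `markov_model`.
#' @param motif IUPAC string or `iupac_motif` (forward strand scored; score
#'   the reverse complement separately for the other strand).
#' @return P(window of length |motif| matches the motif) under the model.
#' @export
motif_prob <- function(model, motif) {
  fwd <- if (inherits(motif, "iupac_motif")) motif$forward else motif
  allowed <- .allowed_idx(fwd)
  k <- length(allowed)
  m <- model$order
  if (m == 0L) {
    p_base <- as.numeric(model$trans[1L, ])
    return(prod(vapply(allowed, function(a) sum(p_base[a + 1L]), 0)))
  }
  if (k < m) stop("motif shorter than model order")
  n_states <- 4L^m
  # state s encodes the last m bases, first base most significant
  # (lexicographic rank of the m-mer)
  digit <- function(s, i) (s %/% 4L^(m - i)) %% 4L
  s_all <- 0:(n_states - 1L)
  mask <- rep(TRUE, n_states)
  for (i in seq_len(m)) {
    mask <- mask & (digit(s_all, i) %in% allowed[[i]])
  }
  p <- as.numeric(model$init) * mask
  if (k > m) {
    n_sub <- 4L^(m - 1L)
    for (j in (m + 1L):k) {
      newp <- numeric(n_states)
      for (b in allowed[[j]]) {
        tmp <- p * model$trans[, b + 1L]
        # aggregate over the oldest base: s and s + d*4^(m-1) share a suffix
        agg <- if (m == 1L) sum(tmp) else rowSums(matrix(tmp, nrow = n_sub))
        newp[(0:(n_sub - 1L)) * 4L + b + 1L] <-
          newp[(0:(n_sub - 1L)) * 4L + b + 1L] + agg
      }
      p <- newp
    }
  }
  sum(p)
}

#' Expected number of motif occurrences in a set of fragments
#'
#' `E = sum_f max(L_f - k + 1, 0) * P(motif)` with the match probability
#' from [motif_prob()]. One strand is scored by default; with
#' `both_strands = TRUE` the forward motif and its reverse complement are
#' scored separately and summed, matching the two-strand convention of
#' [find_motif_occurrences()].
#'
#' @param model A `markov_model`.
#' @param motif IUPAC string or `iupac_motif`.
#' @param fragment_lengths Lengths (bp) of the fragments scanned.
#' @param both_strands Score both strands?
#' @return Expected occurrence count.
#' @export
expected_count <- function(model, motif, fragment_lengths,
                           both_strands = FALSE) {
  fwd <- if (inherits(motif, "iupac_motif")) motif$forward else motif
  k <- nchar(fwd)
  n_windows <- sum(pmax(fragment_lengths - k + 1, 0))
  p <- motif_prob(model, fwd)
  if (both_strands) p <- p + motif_prob(model, revcomp_iupac(fwd))
  n_windows * p
}

#' Coding/intergenic motif usage bias
#'
#' `b = log2(O_ig / E_ig) - log2(O_cds / E_cds)`: negative values mean the
#' motif is used more than expected in coding sequence relative to
#' intergenic sequence (skew toward CDS), positive values the reverse. A
#' zero observed count is replaced by a 0.5 pseudo-observation and flagged.
#'
#' @param O_cds,E_cds Observed and expected counts in coding sequence.
#' @param O_ig,E_ig Observed and expected counts in intergenic sequence.
#' @param tol Absolute bias below which the skew class is `"none"`.
#' @param motif_id Optional identifier carried through.
#' @return List with `motif_id`, `O_cds`, `E_cds`, `O_ig`, `E_ig`, `b`,
#'   `skew_class` (`"CDS"`, `"IG"` or `"none"`) and `pseudo` (TRUE if a zero
#'   count was shifted).
#' @export
usage_bias <- function(O_cds, E_cds, O_ig, E_ig, tol = 1e-8,
                       motif_id = NULL) {
  if (E_cds <= 0 || E_ig <= 0) stop("expected counts must be > 0")
  if (O_cds < 0 || O_ig < 0) stop("observed counts must be >= 0")
  pseudo <- FALSE
  if (O_cds == 0) { O_cds <- 0.5; pseudo <- TRUE }
  if (O_ig == 0) { O_ig <- 0.5; pseudo <- TRUE }
  b <- log2(O_ig / E_ig) - log2(O_cds / E_cds)
  skew <- if (abs(b) < tol) "none" else if (b < 0) "CDS" else "IG"
  list(motif_id = motif_id, O_cds = O_cds, E_cds = E_cds, O_ig = O_ig,
       E_ig = E_ig, b = b, skew_class = skew, pseudo = pseudo)
}

#' Motif usage-bias table for a genome
#'
#' For each motif, counts occurrences fully inside coding (CDS) and
#' intergenic fragments, computes class-specific Markov expectations (one
#' model trained on the concatenated-by-fragment CDS sequence, one on the
#' intergenic fragments, each evaluated on its own class, both strands), and
#' reports the usage-bias statistic together with per-kb observed
#' frequencies. Occurrences straddling a class boundary are counted in
#' neither class.
#'
#' @param genome_seq Genome sequence (character).
#' @param annotation A `genome_annotation`.
#' @param motifs List of `iupac_motif`s (or motif strings, possibly
#'   "forward/reverse").
#' @param order Markov order (default 2).
#' @param pseudocount Pseudocount for model training.
#' @return data.frame with one row per motif: observed/expected counts per
#'   class, per-kb frequencies, bias `b` and `skew_class`.
#' @export
motif_bias_table <- function(genome_seq, annotation, motifs, order = 2,
                             pseudocount = 1) {
  if (is.character(motifs)) motifs <- lapply(motifs, parse_motif)
  if (inherits(motifs, "iupac_motif")) motifs <- list(motifs)
  g <- annotation$genes
  ig <- intergenic_intervals(annotation)
  cds_frags <- substring(genome_seq, g$start + 1L, g$end)
  ig_frags <- substring(genome_seq, ig$start + 1L, ig$end)
  ig_frags <- ig_frags[nchar(ig_frags) > 0]
  model_cds <- train_markov(cds_frags, order, pseudocount)
  model_ig <- train_markov(ig_frags, order, pseudocount)
  cds_ir <- IRanges(start = g$start + 1L, end = g$end)
  ig_ir <- IRanges(start = ig$start + 1L, end = ig$end)
  rows <- lapply(motifs, function(mt) {
    occ <- find_motif_occurrences(genome_seq, mt)
    occ_ir <- IRanges(start = occ$start + 1L, end = occ$end)
    o_cds <- length(unique(queryHits(
      findOverlaps(occ_ir, cds_ir, type = "within"))))
    o_ig <- length(unique(queryHits(
      findOverlaps(occ_ir, ig_ir, type = "within"))))
    e_cds <- expected_count(model_cds, mt, nchar(cds_frags),
                            both_strands = TRUE)
    e_ig <- expected_count(model_ig, mt, nchar(ig_frags),
                           both_strands = TRUE)
    ub <- usage_bias(o_cds, e_cds, o_ig, e_ig, motif_id = mt$id)
    data.frame(motif_id = mt$id, O_cds = o_cds, E_cds = e_cds,
               O_ig = o_ig, E_ig = e_ig,
               per_kb_cds = 1000 * o_cds / sum(nchar(cds_frags)),
               per_kb_ig = 1000 * o_ig / sum(nchar(ig_frags)),
               b = ub$b, skew_class = ub$skew_class, pseudo = ub$pseudo,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
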