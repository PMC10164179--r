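#' Build a position weight matrix from aligned binding sites
#'
#' Column probabilities are `(count_j(b) + pseudocount * background(b)) /
#' (n_sites + pseudocount)`, i.e. pseudocounts are spread according to the
#' background distribution.
#'
#' @param site_seqs Character vector of equal-length binding-site sequences
#'   over `ACGT`.
#' @param pseudocount Total pseudocount per column.
#' @param background Background base probabilities (A,C,G,T), summing to 1.
#' @return A `pwm` object: `probs` (4 x w matrix, rows A,C,G,T),
#'   `background`, `pseudocount`, `width`.
#' @export
build_pwm <- function(site_seqs, pseudocount = 1,
                      background = rep(0.25, 4)) {
  if (length(site_seqs) == 0) stop("no sites")
  site_seqs <- toupper(site_seqs)
  w <- unique(nchar(site_seqs))
  if (length(w) != 1) stop("binding sites must all have equal length")
  if (any(grepl("[^ACGT]", site_seqs))) {
    stop("binding sites must be concrete DNA over ACGT")
  }
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-6)
  mat <- matrix(0, nrow = 4, ncol = w, dimnames = list(.BASES, NULL))
  chars <- do.call(rbind, strsplit(site_seqs, ""))
  for (j in seq_len(w)) {
    tab <- table(factor(chars[, j], levels = .BASES))
    mat[, j] <- as.numeric(tab)
  }
  n <- length(site_seqs)
  probs <- (mat + pseudocount * background) / (n + pseudocount)
  structure(list(probs = probs, background = stats::setNames(background, .BASES),
                 pseudocount = pseudocount, width = w),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> width ", x$width, "\n", sep = "")
  print(round(x$probs, 3))
  invisible(x)
}

# log2 odds score columns, quantized to integer units of `step` bits
.pwm_scores <- function(pwm, step = 1 / 1000) {
  sc <- log2(pwm$probs / pwm$background)
  list(exact = sc, quant = round(sc / step), step = step)
}

#' Exact null distribution of PWM scores
#'
#' Dynamic program over integer-quantized log-odds scores (default
#' quantization 1/1000 bit): the distribution of the total score of a random
#' word drawn from the background model, computed by convolving the
#' per-column score distributions. Exact up to the quantization step.
#'
#' @param pwm A `pwm`.
#' @param step Quantization step in bits.
#' @return List with `scores` (integer score values, in `step` units),
#'   `probs`, and `p_upper` (P(S >= score), aligned with `scores`).
#' @export
pwm_score_distribution <- function(pwm, step = 1 / 1000) {
  qs <- .pwm_scores(pwm, step)$quant
  bg <- pwm$background
  # distribution over quantized total score, kept as prob vector + offset
  probs <- 1
  offset <- 0L
  for (j in seq_len(ncol(qs))) {
    qj <- qs[, j]
    lo <- min(qj); hi <- max(qj)
    newlen <- length(probs) + (hi - lo)
    newp <- numeric(newlen)
    for (b in 1:4) {
      sh <- qj[b] - lo
      idx <- seq_along(probs) + sh
      newp[idx] <- newp[idx] + probs * bg[b]
    }
    probs <- newp
    offset <- offset + lo
  }
  scores <- offset + seq_along(probs) - 1L
  p_upper <- rev(cumsum(rev(probs)))
  list(scores = scores, probs = probs, p_upper = p_upper, step = step)
}

.pwm_pvalue <- function(dist, quant_score) {
  # P(S >= quant_score) under the background null
  idx <- quant_score - dist$scores[1] + 1L
  n <- length(dist$scores)
  out <- numeric(length(quant_score))
  out[idx <= 0] <- 1
  inside <- idx >= 1 & idx <= n
  out[inside] <- dist$p_upper[idx[inside]]
  out[idx > n] <- 0
  out
}

#' Scan a region with a PWM, with exact p-values
#'
#' Both strands are scanned at every offset. The score is the log2-odds of
#' the window under the PWM versus the background; its p-value is the exact
#' upper-tail probability of the quantized score under the background null
#' from [pwm_score_distribution()]. Windows containing `N` are skipped and
#' counted.
#'
#' @param region Region sequence (character).
#' @param pwm A `pwm`.
#' @param region_id Identifier carried into the hits.
#' @param dist Optional precomputed [pwm_score_distribution()] (reuse across
#'   regions for speed).
#' @return data.frame of hits: `region_id`, `start`, `end` (0-based
#'   half-open, region-relative), `strand`, `score` (bits), `p`; attribute
#'   `n_skipped` counts N-containing windows.
#' @export
scan_pwm <- function(region, pwm, region_id = "region", dist = NULL) {
  region <- toupper(region)
  w <- pwm$width
  L <- nchar(region)
  if (L < w) stop("region shorter than PWM width")
  if (is.null(dist)) dist <- pwm_score_distribution(pwm)
  sc <- .pwm_scores(pwm, dist$step)
  base_idx <- match(strsplit(region, "")[[1]], .BASES)  # NA for N
  n_off <- L - w + 1L
  # per-offset score = sum over columns of column score of the window base
  score_fwd <- numeric(n_off); quant_fwd <- integer(n_off)
  score_rev <- numeric(n_off); quant_rev <- integer(n_off)
  ok <- rep(TRUE, n_off)
  for (j in seq_len(w)) {
    b <- base_idx[j:(j + n_off - 1L)]
    ok <- ok & !is.na(b)
    bb <- ifelse(is.na(b), 1L, b)
    score_fwd <- score_fwd + sc$exact[cbind(bb, j)]
    quant_fwd <- quant_fwd + sc$quant[cbind(bb, j)]
    # minus strand: window reverse-complemented, so window position j pairs
    # with PWM column w - j + 1 through the complementary base
    comp <- c(4L, 3L, 2L, 1L)[bb]
    score_rev <- score_rev + sc$exact[cbind(comp, w - j + 1L)]
    quant_rev <- quant_rev + sc$quant[cbind(comp, w - j + 1L)]
  }
  starts <- which(ok) - 1L
  mk <- function(strand, score, quant) {
    data.frame(region_id = region_id, start = starts,
               end = starts + w, strand = strand,
               score = score[ok], p = .pwm_pvalue(dist, quant[ok]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk("+", score_fwd, quant_fwd), mk("-", score_rev, quant_rev))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Extract upstream regions of genes
#'
#' For a plus-strand gene the region is up to `max_len` bp ending at the
#' gene start, truncated at the nearest upstream CDS; for a minus-strand
#' gene the mirrored downstream-in-coordinates region is taken and
#' reverse-complemented. Regions shorter than `min_len` are dropped (the
#' count is reported); regions never overlap a CDS.
#'
#' @param annotation A `genome_annotation`.
#' @param genome Genome sequence (character).
#' @param min_len,max_len Length bounds in bp (defaults 50 and 300).
#' @return data.frame with `gene_id`, `start`, `end` (genome 0-based
#'   half-open), `strand` (gene strand), `seq` (promoter-oriented sequence);
#'   attribute `n_dropped`.
#' @export
extract_upstream <- function(annotation, genome, min_len = 50L,
                             max_len = 300L) {
  g <- annotation$genes
  L <- annotation$genome_length
  cds <- IRanges::reduce(IRanges(start = g$start + 1L, end = g$end))
  n_dropped <- 0L
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "-") {
      cand_s <- g$end[i]
      cand_e <- min(g$end[i] + max_len, L)
    } else {
      cand_s <- max(g$start[i] - max_len, 0L)
      cand_e <- g$start[i]
    }
    if (cand_e <= cand_s) { n_dropped <- n_dropped + 1L; next }
    cand <- IRanges(start = cand_s + 1L, end = cand_e)
    free <- IRanges::setdiff(cand, cds)
    if (length(free) == 0L) { n_dropped <- n_dropped + 1L; next }
    # keep the fragment abutting the gene
    if (g$strand[i] == "-") {
      keep <- free[BiocGenerics::start(free) == cand_s + 1L]
    } else {
      keep <- free[BiocGenerics::end(free) == cand_e]
    }
    if (length(keep) == 0L || BiocGenerics::width(keep) < min_len) {
      n_dropped <- n_dropped + 1L
      next
    }
    s0 <- BiocGenerics::start(keep) - 1L
    e0 <- BiocGenerics::end(keep)
    seq <- substring(genome, s0 + 1L, e0)
    if (g$strand[i] == "-") {
      seq <- as.character(Biostrings::reverseComplement(DNAString(seq)))
    }
    rows[[i]] <- data.frame(gene_id = g$gene_id[i], start = s0, end = e0,
                            strand = g$strand[i], seq = seq,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Filter PWM hits by Benjamini-Hochberg q-value
#'
#' q-values are computed by BH adjustment over all scanned offsets of the
#' analysis (approximating FIMO-style q-values); hits with `q <= q_threshold`
#' are kept.
#'
#' @param hits data.frame of hits carrying `p`.
#' @param q_threshold FDR threshold (default 0.05).
#' @return Filtered hits with a `q` column; attribute `n_tested`.
#' @export
qualify_hits <- function(hits, q_threshold = 0.05) {
  hits$q <- bh_adjust(hits$p)
  out <- hits[hits$q <= q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(hits)
  out
}

#' Annotate TFBS hits with methylation status
#'
#' A hit is `methylated` if at least one methylation call position (either
#' strand) lies within the hit interval (half-open), `non_methylated`
#' otherwise. The association window can be widened by `flank`.
#'
#' @param hits data.frame with genome-coordinate `start`, `end`.
#' @param calls data.frame of methylation calls.
#' @param flank Extra bp added on both sides of each hit (default 0: strict
#'   containment).
#' @return `hits` with a `methylation_status` column.
#' @export
methylation_overlap <- function(hits, calls, flank = 0L) {
  if (nrow(hits) == 0L) {
    hits$methylation_status <- character(0)
    return(hits)
  }
  status <- rep("non_methylated", nrow(hits))
  if (nrow(calls) > 0L) {
    h <- IRanges(start = hits$start + 1L - flank,
                 end = hits$end + flank)
    q <- IRanges(start = calls$position + 1L, width = 1L)
    ov <- findOverlaps(h, q)
    status[unique(queryHits(ov))] <- "methylated"
  }
  hits$methylation_status <- status
  hits
}

#' Scan upstream regions genome-wide and map hits to genome coordinates
#'
#' Convenience pipeline: extract upstream regions, scan each with the PWM,
#' pool all offsets for BH qualification, convert region-relative
#' coordinates back to genome coordinates (accounting for
#' reverse-complemented minus-strand regions), and annotate methylation
#' status.
#'
#' @param annotation A `genome_annotation`.
#' @param genome Genome sequence.
#' @param pwm A `pwm`.
#' @param calls Methylation calls (optional).
#' @param q_threshold FDR threshold.
#' @param min_len,max_len Upstream-region length bounds.
#' @return data.frame of qualified hits in genome coordinates with
#'   `methylation_status`.
#' @export
tfbs_scan_genome <- function(annotation, genome, pwm, calls = NULL,
                             q_threshold = 0.05, min_len = 50L,
                             max_len = 300L) {
  regions <- extract_upstream(annotation, genome, min_len, max_len)
  if (nrow(regions) == 0L) {
    return(data.frame(region_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0), q = numeric(0),
                      methylation_status = character(0),
                      stringsAsFactors = FALSE))
  }
  dist <- pwm_score_distribution(pwm)
  all_hits <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (nchar(r$seq) < pwm$width) return(NULL)
    h <- scan_pwm(r$seq, pwm, region_id = r$gene_id, dist = dist)
    if (r$strand == "-") {
      # region seq is the reverse complement of [start, end)
      len <- r$end - r$start
      gs <- r$start + (len - h$end)
      h$end <- gs + pwm$width
      h$start <- gs
      h$strand <- ifelse(h$strand == "+", "-", "+")
    } else {
      h$start <- h$start + r$start
      h$end <- h$end + r$start
    }
    h
  })
  hits <- do.call(rbind, all_hits)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(hits)
  }
  kept <- qualify_hits(hits, q_threshold)
  if (!is.null(calls)) kept <- methylation_overlap(kept, calls)
  kept
}
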