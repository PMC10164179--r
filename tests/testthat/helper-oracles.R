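# Independent oracles and small fixture builders used across test files.
# Oracles deliberately avoid the package's own computation paths.

# --- fixtures ---------------------------------------------------------------

make_annotation <- function(genome_length, starts, ends,
                            strands = NULL, cog = NULL, ko = NULL) {
  n <- length(starts)
  if (is.null(strands)) strands <- rep_len(c("+", "-"), n)
  genome_annotation(genome_length, data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    start = starts, end = ends, strand = strands,
    cog = if (is.null(cog)) rep(NA_character_, n) else cog,
    ko = if (is.null(ko)) rep(NA_character_, n) else ko,
    stringsAsFactors = FALSE))
}

# background annotation for enrichment tests: `cat_size` genes in the focal
# category, the rest spread over other letters
make_enrich_annotation <- function(n_genes = 2000, cat_size = 200,
                                   category = "G") {
  others <- setdiff(LETTERS[3:22], category)
  cog <- c(rep(category, cat_size),
           rep_len(others, n_genes - cat_size))
  make_annotation(genome_length = n_genes * 1500,
                  starts = (seq_len(n_genes) - 1L) * 1500L,
                  ends = (seq_len(n_genes) - 1L) * 1500L + 1000L,
                  cog = cog)
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# --- motif occurrence oracle: regex with lookahead (overlapping matches) ----

iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(motif, "")[[1]]], collapse = "")
}

occurrences_oracle <- function(seq, forward) {
  k <- nchar(forward)
  scan1 <- function(pat, strand) {
    hits <- gregexpr(paste0("(?=", iupac_regex(pat), ")"), seq,
                     perl = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    data.frame(start = as.integer(hits) - 1L,
               end = as.integer(hits) - 1L + k,
               strand = strand, stringsAsFactors = FALSE)
  }
  rc <- paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
                                  forward), "")[[1]]), collapse = "")
  out <- rbind(scan1(forward, "+"), scan1(rc, "-"))
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- Fisher exact oracle: hypergeometric enumeration ------------------------

fisher_oracle <- function(a, b, c, d, slack = 1e-7) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; N <- m1 + m2
  if (N == 0) return(1)
  klo <- max(0, n1 - m2); khi <- min(n1, m1)
  ks <- klo:khi
  mass <- exp(lchoose(m1, ks) + lchoose(m2, n1 - ks) - lchoose(N, n1))
  obs <- mass[a - klo + 1]
  sum(mass[mass <= obs * (1 + slack)])
}

# --- BH oracle: literal step-up formula ------------------------------------

bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# --- Markov chain-probability oracle (explicit expansion) -------------------

chain_prob_oracle <- function(model, word) {
  m <- model$order
  bases <- strsplit(word, "")[[1]]
  if (m == 0) return(prod(model$trans[1, bases]))
  ctx <- paste(bases[1:m], collapse = "")
  p <- model$init[[ctx]]
  if (length(bases) > m) {
    for (j in (m + 1):length(bases)) {
      ctx <- paste(bases[(j - m):(j - 1)], collapse = "")
      p <- p * model$trans[ctx, bases[j]]
    }
  }
  p
}

motif_prob_oracle <- function(model, motif_string) {
  sum(vapply(expand_iupac(motif_string), chain_prob_oracle, 0,
             model = model))
}

# --- PWM p-value oracle: enumeration of all 4^w words -----------------------

pwm_enum_distribution <- function(pwm, step = 1 / 1000) {
  w <- pwm$width
  qs <- round(log2(pwm$probs / pwm$background) / step)
  words <- expand.grid(rep(list(1:4), w))
  score <- as.integer(rowSums(sapply(seq_len(w),
                                     function(j) qs[words[[j]], j])))
  prob <- apply(sapply(seq_len(w),
                       function(j) pwm$background[words[[j]]]), 1, prod)
  data.frame(score = score, prob = prob)
}

pwm_pvalue_oracle <- function(enum, quant_score) {
  vapply(quant_score, function(s) sum(enum$prob[enum$score >= s]), 0)
}

# --- binomial upper-tail oracle by direct summation -------------------------

binom_upper_oracle <- function(x, size, prob) {
  sum(stats::dbinom(x:size, size, prob))
}
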