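#' @importFrom Biostrings DNAString DNAStringSet matchPattern IUPAC_CODE_MAP
NULL

# IUPAC complement table (covers the full degenerate alphabet)
.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.check_iupac <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(chars, names(.IUPAC_COMPLEMENT))
  if (length(bad) > 0L) {
    stop("illegal IUPAC character(s) in motif: ", paste(unique(bad), collapse = ", "))
  }
  paste(chars, collapse = "")
}

#' Reverse-complement a degenerate IUPAC string
#'
#' @param x IUPAC DNA string (characters in `ACGTRYSWKMBDHVN`).
#' @return The reverse complement, using the IUPAC complement rules
#'   (e.g. `R` (A/G) complements to `Y` (C/T)).
#' @examples
#' revcomp_iupac("ACRCAG")   # "CTGYGT"
#' @export
revcomp_iupac <- function(x) {
  x <- .check_iupac(x)
  chars <- rev(strsplit(x, "")[[1]])
  paste(.IUPAC_COMPLEMENT[chars], collapse = "")
}

#' Construct a degenerate methylation motif
#'
#' A motif is a short IUPAC string recognized by a DNA methyltransferase.
#' Palindromic motifs come as "forward/reverse" pairs in which the reverse
#' partner is the IUPAC reverse complement of the forward string; when a
#' `reverse` partner is supplied it is checked against that rule.
#'
#' @param forward IUPAC string of the forward motif.
#' @param reverse Optional reverse partner; must equal
#'   `revcomp_iupac(forward)`.
#' @param methylated_offset Optional 0-based index of the methylated adenine
#'   within `forward` (the base must be able to be an A).
#' @param id Optional motif identifier.
#' @return An object of class `iupac_motif`.
#' @examples
#' iupac_motif("GCCAT", "ATGGC", methylated_offset = 3)
#' @export
iupac_motif <- function(forward, reverse = NULL, methylated_offset = NULL,
                        id = NULL) {
  forward <- .check_iupac(forward)
  if (nchar(forward) == 0L) stop("motif must be non-empty")
  if (!is.null(reverse)) {
    reverse <- .check_iupac(reverse)
    if (reverse != revcomp_iupac(forward)) {
      stop("reverse partner '", reverse, "' is not the IUPAC reverse ",
           "complement of '", forward, "'")
    }
  }
  if (!is.null(methylated_offset)) {
    stopifnot(methylated_offset >= 0, methylated_offset < nchar(forward))
    base <- substr(forward, methylated_offset + 1L, methylated_offset + 1L)
    if (!grepl("A", IUPAC_CODE_MAP[[base]], fixed = TRUE)) {
      stop("methylated_offset does not point at a base that can be adenine")
    }
  }
  structure(
    list(forward = forward, reverse = reverse,
         methylated_offset = methylated_offset,
         id = if (is.null(id)) forward else id),
    class = "iupac_motif"
  )
}

#' Parse a "forward/reverse" motif string
#'
#' @param x A motif string, either plain (`"CTGCAG"`) or a palindromic pair
#'   (`"GCCAT/ATGGC"`).
#' @param ... Passed to [iupac_motif()].
#' @return An `iupac_motif`.
#' @export
parse_motif <- function(x, ...) {
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    iupac_motif(parts[1], ...)
  } else if (length(parts) == 2L) {
    iupac_motif(parts[1], parts[2], ...)
  } else {
    stop("cannot parse motif string: ", x)
  }
}

#' @export
print.iupac_motif <- function(x, ...) {
  lab <- if (is.null(x$reverse)) x$forward else paste0(x$forward, "/", x$reverse)
  cat("<iupac_motif> ", lab, "\n", sep = "")
  if (!is.null(x$methylated_offset)) {
    cat("  methylated adenine at 0-based offset ", x$methylated_offset, "\n",
        sep = "")
  }
  invisible(x)
}

#' Expand a degenerate motif to all concrete DNA words
#'
#' Used as a brute-force route for expectation and oracle checks; the number
#' of concrete words is guarded because N-runs explode combinatorially.
#'
#' @param motif IUPAC string or `iupac_motif`.
#' @param max_words Guard on the expansion size.
#' @return Character vector of concrete words over `ACGT`.
#' @export
expand_iupac <- function(motif, max_words = 1e6) {
  fwd <- if (inherits(motif, "iupac_motif")) motif$forward else .check_iupac(motif)
  sets <- lapply(strsplit(fwd, "")[[1]],
                 function(ch) strsplit(IUPAC_CODE_MAP[[ch]], "")[[1]])
  n_words <- prod(vapply(sets, length, 1L))
  if (n_words > max_words) {
    stop("motif expands to ", n_words, " concrete words (> ", max_words, ")")
  }
  apply(do.call(expand.grid,
                c(rev(sets), stringsAsFactors = FALSE)), 1L,
        function(r) paste(rev(r), collapse = ""))
}

#' Find all occurrences of a degenerate motif on both strands
#'
#' Reports every plus-strand match of the forward string and every match of
#' its reverse complement (reported on the minus strand), in genome
#' coordinates (0-based, half-open). Overlapping matches are all reported.
#' For a self-reverse-complementary (palindromic) motif the same interval
#' appears once per strand; use [count_motif_dyads()] to count dyads once.
#'
#' @param seq Genome sequence (character string over `ACGTN`).
#' @param motif An `iupac_motif` (or IUPAC string).
#' @return A data.frame with columns `start`, `end` (0-based half-open) and
#'   `strand` (`+`/`-`), ordered by `start` then strand.
#' @examples
#' m <- iupac_motif("GCCAT")
#' find_motif_occurrences("AAGCCATAA", m)
#' @export
find_motif_occurrences <- function(seq, motif) {
  if (!inherits(motif, "iupac_motif")) motif <- iupac_motif(motif)
  seq <- toupper(seq)
  if (nchar(motif$forward) > nchar(seq)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  subject <- DNAString(seq)
  scan1 <- function(pattern, strand) {
    hits <- matchPattern(DNAString(pattern), subject,
                         fixed = c(pattern = FALSE, subject = TRUE))
    if (length(hits) == 0L) {
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE))
    }
    data.frame(start = BiocGenerics::start(hits) - 1L,
               end = BiocGenerics::end(hits),
               strand = strand, stringsAsFactors = FALSE)
  }
  fwd <- scan1(motif$forward, "+")
  rc <- revcomp_iupac(motif$forward)
  rev <- scan1(rc, "-")
  out <- rbind(fwd, rev)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count motif occurrences as dyads
#'
#' A palindromic motif matches the same interval on both strands; reported
#' motif tables count one occurrence per dyad (one double-stranded site), so
#' intervals are deduplicated across strands here.
#'
#' @param occurrences Output of [find_motif_occurrences()].
#' @return Integer count of distinct intervals.
#' @export
count_motif_dyads <- function(occurrences) {
  if (nrow(occurrences) == 0L) return(0L)
  nrow(unique(occurrences[, c("start", "end")]))
}
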