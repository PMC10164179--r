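#' @importFrom stats fisher.test p.adjust cor median
NULL

#' Threshold filter for differential-expression / protein tables
#'
#' Splits a differential table into up- and downregulated identifiers using
#' a fold-change threshold and a significance rule. RNA-seq style filtering
#' uses `padj <= 0.05` with a 2.0-fold change; proteomics style uses raw
#' `p < 0.05` with a 1.2-fold change.
#'
#' @param table data.frame with columns `id`, `log2fc` and `padj` (for
#'   `use = "padj"`) or `p` (for `use = "p"`).
#' @param fc_threshold Fold-change threshold (> 1), on the linear scale.
#' @param use Significance rule: `"padj"` (padj <= 0.05) or `"p"`
#'   (p < 0.05).
#' @return List with `up` and `down` character vectors of ids.
#' @export
filter_differential <- function(table, fc_threshold = 2,
                                use = c("padj", "p")) {
  use <- match.arg(use)
  need <- c("id", "log2fc", use)
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "))
  }
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  sig <- if (use == "padj") table$padj <= 0.05 else table$p < 0.05
  sig[is.na(sig)] <- FALSE
  lfc <- log2(fc_threshold)
  list(up = table$id[sig & table$log2fc >= lfc],
       down = table$id[sig & table$log2fc <= -lfc])
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Probability-mass rule: the p-value sums the hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table (with a small relative slack for floating-point
#' ties), i.e. the classical two-sided exact test.
#'
#' @param a,b,c,d Cell counts (row-wise: `a b / c d`).
#' @return Two-sided p-value; an all-zero table returns 1.
#' @examples
#' fisher_two_sided(3, 1, 1, 3)   # 0.4857143
#' @export
fisher_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("cell counts must be nonnegative integers")
  }
  if (sum(counts) == 0) return(1)
  min(1, fisher.test(matrix(counts, nrow = 2, byrow = TRUE),
                     alternative = "two.sided")$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * N / j`, capped at 1
#' and mapped back to the input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) > 0 &&
      (any(pvals < 0, na.rm = TRUE) || any(pvals > 1, na.rm = TRUE))) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Functional-category enrichment of a differential gene set
#'
#' Builds a 2x2 table per category (`k` differential genes in the category,
#' `n - k` differential outside, `K - k` non-differential in the category,
#' `N - K - n + k` remaining), tests each with the two-sided Fisher exact
#' test, and adjusts across categories by Benjamini-Hochberg. The background
#' is the set of annotated genes carrying the chosen tag.
#'
#' @param de_ids Character vector of differential gene ids (subset of the
#'   annotation's gene ids).
#' @param annotation A `genome_annotation` with `cog`/`ko` tags.
#' @param key `"cog"` or `"ko"`.
#' @return data.frame with one row per category: `category`, `k`, `K`, `n`,
#'   `N`, `odds_ratio`, `p`, `q`, `significant` (raw p < 0.05).
#' @export
category_enrichment <- function(de_ids, annotation, key = c("cog", "ko")) {
  key <- match.arg(key)
  g <- annotation$genes
  tag <- g[[key]]
  keep <- !is.na(tag) & nzchar(tag)
  if (!any(keep)) stop("empty background: no gene carries a '", key, "' tag")
  bg_ids <- g$gene_id[keep]
  bg_tag <- tag[keep]
  unknown <- setdiff(de_ids, g$gene_id)
  if (length(unknown) > 0) {
    stop("differential ids absent from annotation: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  de_in_bg <- intersect(de_ids, bg_ids)
  if (length(de_in_bg) < length(intersect(de_ids, g$gene_id))) {
    warning(length(de_ids) - length(de_in_bg),
            " differential gene(s) lack a '", key,
            "' tag and are outside the background")
  }
  N <- length(bg_ids)
  n <- length(de_in_bg)
  is_de <- bg_ids %in% de_in_bg
  cats <- sort(unique(bg_tag))
  rows <- lapply(cats, function(cat) {
    in_cat <- bg_tag == cat
    K <- sum(in_cat)
    k <- sum(in_cat & is_de)
    tab <- c(k, n - k, K - k, N - K - n + k)
    p <- fisher_two_sided(tab[1], tab[2], tab[3], tab[4])
    or <- (tab[1] * tab[4]) / max(tab[2] * tab[3], .Machine$double.xmin)
    data.frame(category = cat, k = k, K = K, n = n, N = N,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out
}

#' Relative expression by the comparative threshold-cycle method
#'
#' `2^-ddCT` with
#' `ddCT = (CT_target,test - CT_ref,test) - (CT_target,ctrl - CT_ref,ctrl)`.
#'
#' @param ct_target_test,ct_ref_test CT of target and reference gene in the
#'   test condition.
#' @param ct_target_ctrl,ct_ref_ctrl Same in the control condition.
#' @return Relative expression (fold change).
#' @export
ddct <- function(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(ct_target_test > 0, ct_ref_test > 0,
            ct_target_ctrl > 0, ct_ref_ctrl > 0)
  dd <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-dd)
}

#' Sample Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Pearson r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y")
  }
  cor(x, y, method = "pearson")
}
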