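#' @importFrom stats pbinom
NULL

#' Construct a contact matrix
#'
#' @param mat Symmetric nonnegative matrix of contact counts (raw integers)
#'   or balanced reals.
#' @param bin_size Bin width in bp.
#' @param circular Is the chromosome circular?
#' @param balanced Has the matrix been balanced?
#' @return A `contact_matrix`.
#' @export
contact_matrix <- function(mat, bin_size = 1000L, circular = TRUE,
                           balanced = FALSE) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-8) stop("contact matrix must be symmetric")
  if (any(mat < 0)) stop("contact counts must be nonnegative")
  if (!balanced && any(mat != floor(mat))) {
    stop("raw contact counts must be integers")
  }
  structure(list(mat = mat, n_bins = nrow(mat),
                 bin_size = as.integer(bin_size),
                 circular = circular, balanced = balanced),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", x$n_bins, " bins x ", x$bin_size, " bp",
      if (x$circular) ", circular" else "",
      if (x$balanced) ", balanced" else ", raw", "\n", sep = "")
  invisible(x)
}

#' Circular bin distance
#'
#' @param i,j Bin indices (0-based).
#' @param n_bins Number of bins.
#' @param circular Wrap around the origin?
#' @return `min(|i-j|, n_bins - |i-j|)` for circular chromosomes.
#' @export
bin_distance <- function(i, j, n_bins, circular = TRUE) {
  d <- abs(i - j)
  if (circular) pmin(d, n_bins - d) else d
}

#' Bin a pair list into a contact matrix
#'
#' @param pairs data.frame with `bin_i`, `bin_j` (0-based), `count`.
#' @param n_bins Number of bins.
#' @param bin_size Bin width in bp.
#' @param circular Circular chromosome?
#' @return A `contact_matrix` with symmetric accumulation (diagonal kept).
#' @export
bin_contacts <- function(pairs, n_bins, bin_size = 1000L, circular = TRUE) {
  M <- matrix(0, n_bins, n_bins)
  if (nrow(pairs) > 0L) {
    if (any(pairs$bin_i < 0) || any(pairs$bin_j < 0) ||
        any(pairs$bin_i >= n_bins) || any(pairs$bin_j >= n_bins)) {
      stop("bin index out of range [0, n_bins)")
    }
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$bin_i[r] + 1L
      j <- pairs$bin_j[r] + 1L
      M[i, j] <- M[i, j] + pairs$count[r]
      if (i != j) M[j, i] <- M[j, i] + pairs$count[r]
    }
  }
  contact_matrix(M, bin_size = bin_size, circular = circular)
}

#' Matrix to canonical pair list
#'
#' @param cm A `contact_matrix`.
#' @return data.frame `bin_i <= bin_j` (0-based), `count`, nonzero entries
#'   of the upper triangle plus diagonal.
#' @export
contacts_to_pairs <- function(cm) {
  idx <- which(upper.tri(cm$mat, diag = TRUE) & cm$mat != 0, arr.ind = TRUE)
  out <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                    count = cm$mat[idx])
  out <- out[order(out$bin_i, out$bin_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Iteratively divides rows and columns by their relative coverage until the
#' coefficient of variation of row sums falls below `tol`. All-zero bins are
#' masked (excluded from the CV and left at zero) and reported. Returns the
#' balanced matrix and the per-bin bias vector with
#' `M_bal[i,j] = M[i,j] / (b_i * b_j)`.
#'
#' @param cm A raw `contact_matrix`.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the CV of unmasked row sums.
#' @return List with `matrix` (balanced `contact_matrix`), `bias`, `masked`
#'   (0-based indices of masked bins), `iterations`, `cv`.
#' @export
ice_balance <- function(cm, max_iter = 200L, tol = 1e-5) {
  M <- cm$mat
  masked <- which(rowSums(M) == 0)
  active <- setdiff(seq_len(nrow(M)), masked)
  if (length(active) == 0L) stop("all bins are empty")
  bias <- rep(1, nrow(M))
  cv <- Inf
  for (it in seq_len(max_iter)) {
    s <- rowSums(M)[active]
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv)) cv <- 0  # single active bin
    if (cv < tol) break
    db <- rep(1, nrow(M))
    db[active] <- s / mean(s)
    bias <- bias * db
    M <- M / outer(db, db)
  }
  if (cv >= tol) {
    stop("ICE did not converge in ", max_iter, " iterations (CV = ",
         signif(cv, 4), ")")
  }
  out <- cm
  out$mat <- M
  out$balanced <- TRUE
  list(matrix = out, bias = bias, masked = masked - 1L, iterations = it,
       cv = cv)
}

# mean balanced contact per circular distance (index d+1 = distance d)
.distance_means <- function(mat, circular = TRUE) {
  n <- nrow(mat)
  dmax <- if (circular) n %/% 2 else n - 1L
  ii <- row(mat); jj <- col(mat)
  d <- bin_distance(ii - 1L, jj - 1L, n, circular)
  ut <- upper.tri(mat)
  tapply(mat[ut], factor(d[ut], levels = 1:dmax), mean)
}

#' Call significant Hi-C interactions
#'
#' Distance-stratified binomial model: the expected contact probability of a
#' pair at circular distance d is the mean balanced contact at d divided by
#' the total over all tested pairs; the p-value is the upper-tail binomial
#' probability of the observed raw count given the total raw count, and
#' q-values are BH-adjusted over all tested pairs. A call requires
#' `p < p_threshold`, `q < q_threshold` and raw `count > min_count`
#' (defaults 0.01 / 0.01 / 2). The diagonal is not tested.
#'
#' @param cm_raw Raw `contact_matrix`.
#' @param cm_bal Balanced `contact_matrix` (same shape).
#' @param p_threshold,q_threshold,min_count Filter thresholds.
#' @return data.frame of tested pairs (`bin_i`, `bin_j` 0-based, `count`,
#'   `expected`, `p`, `q`, `significant`); the significant subset also in
#'   attribute-free form via `significant == TRUE`.
#' @export
call_significant <- function(cm_raw, cm_bal, p_threshold = 0.01,
                             q_threshold = 0.01, min_count = 2) {
  stopifnot(cm_raw$n_bins == cm_bal$n_bins)
  n <- cm_raw$n_bins
  if (n == 0L) return(data.frame())
  mean_bal <- .distance_means(cm_bal$mat, cm_bal$circular)
  ut <- which(upper.tri(cm_raw$mat), arr.ind = TRUE)
  d <- bin_distance(ut[, 1] - 1L, ut[, 2] - 1L, n, cm_raw$circular)
  mb <- as.numeric(mean_bal[d])
  mb[is.na(mb)] <- 0
  counts <- cm_raw$mat[upper.tri(cm_raw$mat)]
  keep <- mb > 0
  N_total <- sum(counts[keep])
  p_pair <- mb[keep] / sum(mb[keep])
  obs <- counts[keep]
  pvals <- pbinom(obs - 1, N_total, p_pair, lower.tail = FALSE)
  out <- data.frame(bin_i = ut[keep, 1] - 1L, bin_j = ut[keep, 2] - 1L,
                    count = obs, expected = N_total * p_pair, p = pvals)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < p_threshold & out$q < q_threshold &
    out$count > min_count
  out <- out[order(out$bin_i, out$bin_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Insulation profile of a contact map
#'
#' `s(i)` is the mean balanced contact in the `w x w` square of pairs
#' immediately upstream x downstream of bin i (circular wrap); the
#' normalized score is `n(i) = log2(s(i) / mean(s))`. Minima of `n` mark
#' domain boundaries.
#'
#' @param cm_bal Balanced `contact_matrix`.
#' @param w Window half-size in bins (>= 2).
#' @return An `insulation_profile`: `score` (s), `norm` (n), `w`.
#' @export
insulation_profile <- function(cm_bal, w = 10L) {
  if (w < 2) stop("window must be >= 2 bins")
  n <- cm_bal$n_bins
  if (n <= 2 * w) stop("need n_bins > 2w")
  M <- cm_bal$mat
  s <- numeric(n)
  for (i in seq_len(n)) {
    up <- ((i - 1L - seq_len(w)) %% n) + 1L       # bins i-w .. i-1
    down <- ((i - 1L + seq_len(w)) %% n) + 1L     # bins i+1 .. i+w
    s[i] <- mean(M[up, down])
  }
  norm <- log2(s / mean(s))
  structure(list(score = s, norm = norm, w = as.integer(w), n_bins = n),
            class = "insulation_profile")
}

#' @export
print.insulation_profile <- function(x, ...) {
  cat("<insulation_profile> ", x$n_bins, " bins, window ", x$w, "\n",
      sep = "")
  invisible(x)
}

#' Call chromosomal interaction domains from an insulation profile
#'
#' Boundaries are local minima of the normalized insulation score whose
#' boundary strength - the mean score over `delta_span` bins on the left
#' minus the minimum, plus the right-side analog - reaches `strength_min`.
#' CIDs are the arcs between consecutive boundaries on the circular
#' chromosome; with no qualifying boundary a single whole-circle CID is
#' returned.
#'
#' @param profile An `insulation_profile`.
#' @param delta_span Bins averaged on each side for the strength (default 5).
#' @param strength_min Minimum boundary strength in log2 units (default 0.5).
#' @return List with `boundaries` (0-based bins, with `strength`) and `cids`
#'   (data.frame `start_bin`, `end_bin` half-open in bins; a CID may wrap,
#'   in which case `end_bin <= start_bin`).
#' @export
call_cids <- function(profile, delta_span = 5L, strength_min = 0.5) {
  n <- profile$n_bins
  x <- profile$norm
  idx <- seq_len(n)
  left1 <- ((idx - 2L) %% n) + 1L
  right1 <- (idx %% n) + 1L
  is_min <- x < x[left1] & x <= x[right1]
  strength <- numeric(n)
  for (i in which(is_min)) {
    left <- ((i - 1L - seq_len(delta_span)) %% n) + 1L
    right <- ((i - 1L + seq_len(delta_span)) %% n) + 1L
    strength[i] <- (mean(x[left]) - x[i]) + (mean(x[right]) - x[i])
  }
  bnd <- which(is_min & strength >= strength_min)
  if (length(bnd) == 0L) {
    return(list(
      boundaries = data.frame(bin = integer(0), strength = numeric(0)),
      cids = data.frame(start_bin = 0L, end_bin = n)
    ))
  }
  b0 <- sort(bnd) - 1L  # 0-based boundary bins
  if (length(b0) == 1L) {
    cids <- data.frame(start_bin = b0, end_bin = b0)  # whole circle, wraps
  } else {
    cids <- data.frame(start_bin = b0,
                       end_bin = c(b0[-1], b0[1]))
  }
  list(boundaries = data.frame(bin = b0, strength = strength[bnd][order(bnd)]),
       cids = cids)
}

# bins covered by a (possibly wrapping) half-open bin interval
.cid_bins <- function(start_bin, end_bin, n_bins) {
  if (end_bin > start_bin) {
    start_bin:(end_bin - 1L)
  } else {
    c(start_bin:(n_bins - 1L), if (end_bin > 0) 0:(end_bin - 1L))
  }
}

#' Condition-unique interactions and CIDs
#'
#' An interaction is unique to one condition iff its bin pair passes the
#' significance filters there and not in the other. A CID is unique iff no
#' CID of the other condition matches it at reciprocal overlap
#' `>= cid_reciprocal_overlap` (overlap computed on circular bin sets).
#'
#' @param sig_a,sig_b Outputs of [call_significant()] for the two
#'   conditions.
#' @param cids_a,cids_b CID data.frames from [call_cids()] (optional).
#' @param n_bins Number of bins (needed for circular CID overlap).
#' @param cid_reciprocal_overlap Reciprocal-overlap threshold (default 0.8).
#' @return List with `interactions_unique_a`, `interactions_unique_b`
#'   (pair data.frames) and, when CIDs are supplied, `cids_unique_a`,
#'   `cids_unique_b`.
#' @export
unique_elements <- function(sig_a, sig_b, cids_a = NULL, cids_b = NULL,
                            n_bins = NULL, cid_reciprocal_overlap = 0.8) {
  key <- function(df) paste(df$bin_i, df$bin_j, sep = ":")
  pass_a <- sig_a[sig_a$significant, , drop = FALSE]
  pass_b <- sig_b[sig_b$significant, , drop = FALSE]
  ua <- pass_a[!(key(pass_a) %in% key(pass_b)), , drop = FALSE]
  ub <- pass_b[!(key(pass_b) %in% key(pass_a)), , drop = FALSE]
  rownames(ua) <- rownames(ub) <- NULL
  out <- list(interactions_unique_a = ua, interactions_unique_b = ub)
  if (!is.null(cids_a) && !is.null(cids_b)) {
    if (is.null(n_bins)) stop("n_bins required for CID matching")
    binsets <- function(cids) lapply(seq_len(nrow(cids)), function(k) {
      .cid_bins(cids$start_bin[k], cids$end_bin[k], n_bins)
    })
    sa <- binsets(cids_a); sb <- binsets(cids_b)
    matched <- function(x, others) {
      any(vapply(others, function(y) {
        ov <- length(intersect(x, y))
        ov / length(x) >= cid_reciprocal_overlap &&
          ov / length(y) >= cid_reciprocal_overlap
      }, TRUE))
    }
    out$cids_unique_a <- cids_a[!vapply(sa, matched, TRUE, others = sb), ,
                                drop = FALSE]
    out$cids_unique_b <- cids_b[!vapply(sb, matched, TRUE, others = sa), ,
                                drop = FALSE]
    rownames(out$cids_unique_a) <- rownames(out$cids_unique_b) <- NULL
  }
  out
}

#' Condition-unique insulation regions
#'
#' Sliding windows (length `window_bins`, step 1, circular) over the two
#' normalized insulation profiles are compared by Pearson correlation;
#' windows with `r > r_threshold` are concordant and the union of their bins
#' is removed. Maximal runs of the remaining bins are returned as the unique
#' insulation regions. A window with zero variance in either profile is
#' concordant iff both windows are flat.
#'
#' @param profile_a,profile_b `insulation_profile`s of equal length.
#' @param window_bins Window length in bins (default 20).
#' @param r_threshold Pearson threshold (default 0.6).
#' @return data.frame of regions (`start_bin`, `end_bin`, half-open; a
#'   region may wrap with `end_bin <= start_bin`); zero rows if profiles
#'   agree everywhere.
#' @export
unique_insulation_regions <- function(profile_a, profile_b,
                                      window_bins = 20L, r_threshold = 0.6) {
  stopifnot(profile_a$n_bins == profile_b$n_bins)
  n <- profile_a$n_bins
  xa <- profile_a$norm; xb <- profile_b$norm
  concordant_bin <- rep(FALSE, n)
  for (s in 0:(n - 1L)) {
    bins <- ((s + 0:(window_bins - 1L)) %% n) + 1L
    wa <- xa[bins]; wb <- xb[bins]
    va <- stats::var(wa); vb <- stats::var(wb)
    if (va == 0 || vb == 0) {
      conc <- va == 0 && vb == 0
    } else {
      conc <- cor(wa, wb) > r_threshold
    }
    if (conc) concordant_bin[bins] <- TRUE
  }
  remaining <- which(!concordant_bin) - 1L
  if (length(remaining) == 0L) {
    return(data.frame(start_bin = integer(0), end_bin = integer(0)))
  }
  if (length(remaining) == n) {
    return(data.frame(start_bin = 0L, end_bin = 0L))  # whole circle
  }
  # maximal circular runs
  inreg <- !concordant_bin
  starts <- which(inreg & !inreg[((0:(n - 1L) - 1L) %% n) + 1L])
  regions <- lapply(starts, function(s) {
    e <- s  # run covers 1-based bins s..e; extend while the next bin is in
    while (inreg[(e %% n) + 1L]) e <- e + 1L
    data.frame(start_bin = s - 1L,
               end_bin = if (e <= n) e else e - n)  # wraps iff e > n
  })
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Genes overlapping bin regions
#'
#' A gene is counted iff its interval overlaps the bp span of any region by
#' at least 1 bp; genes are deduplicated across the regions of a class.
#'
#' @param regions data.frame with `start_bin`, `end_bin` (half-open bin
#'   units; wrapping regions allowed with `end_bin <= start_bin`).
#' @param bin_size Bin width in bp.
#' @param annotation A `genome_annotation`.
#' @param n_bins Number of bins (needed to resolve wrapped regions).
#' @return Character vector of unique gene ids.
#' @export
genes_in_regions <- function(regions, bin_size, annotation, n_bins = NULL) {
  g <- annotation$genes
  if (nrow(g) == 0L || nrow(regions) == 0L) return(character(0))
  spans <- list()
  for (k in seq_len(nrow(regions))) {
    s <- regions$start_bin[k]; e <- regions$end_bin[k]
    if (e > s) {
      spans[[length(spans) + 1L]] <- c(s * bin_size, e * bin_size)
    } else {
      if (is.null(n_bins)) stop("n_bins required for wrapped regions")
      spans[[length(spans) + 1L]] <- c(s * bin_size, n_bins * bin_size)
      if (e > 0) spans[[length(spans) + 1L]] <- c(0, e * bin_size)
    }
  }
  sp <- do.call(rbind, spans)
  reg_ir <- IRanges(start = sp[, 1] + 1L, end = sp[, 2])
  gene_ir <- IRanges(start = g$start + 1L, end = g$end)
  ov <- findOverlaps(gene_ir, reg_ir)
  unique(g$gene_id[queryHits(ov)])
}
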