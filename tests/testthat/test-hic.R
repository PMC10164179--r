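test_that("binning accumulates symmetrically and conserves mass", {
  pairs <- data.frame(bin_i = c(3L, 5L), bin_j = c(5L, 3L),
                      count = c(2L, 1L))
  cm <- bin_contacts(pairs, 10)
  expect_equal(cm$mat[4, 6], 3)
  expect_equal(cm$mat[6, 4], 3)

  cm0 <- bin_contacts(pairs[0, ], 10)
  expect_true(all(cm0$mat == 0))

  set.seed(30)
  pr <- data.frame(bin_i = sample(0:19, 50, TRUE),
                   bin_j = sample(0:19, 50, TRUE),
                   count = sample(1:5, 50, TRUE))
  cm2 <- bin_contacts(pr, 20)
  mass <- sum(cm2$mat[upper.tri(cm2$mat, diag = TRUE)])
  expect_equal(mass, sum(pr$count))

  expect_error(bin_contacts(data.frame(bin_i = 25L, bin_j = 1L,
                                       count = 1L), 20), "out of range")
})

test_that("ICE balancing equalizes coverage and is idempotent", {
  const <- contact_matrix(matrix(5, 6, 6))
  b <- ice_balance(const)
  expect_equal(b$cv, 0, tolerance = 1e-12)
  expect_equal(b$matrix$mat, const$mat)

  r1 <- contact_matrix(matrix(c(4, 2, 2, 1), 2, 2))
  b1 <- ice_balance(r1)
  rs <- rowSums(b1$matrix$mat)
  expect_lt(abs(rs[1] - rs[2]) / mean(rs), 1e-4)
  expect_equal(b1$matrix$mat[1, 2] * b1$bias[1] * b1$bias[2], 2,
               tolerance = 1e-6)

  set.seed(31)
  cfg <- synth_config(seed = 31, hic_bins = 50, cid_blocks = NULL,
                      diff_contacts = NULL)
  h <- gen_hic_pair(cfg)
  b2 <- ice_balance(h$ref)
  again <- ice_balance(contact_matrix(b2$matrix$mat, balanced = TRUE))
  expect_lt(max(abs(again$matrix$mat - b2$matrix$mat) /
                  mean(b2$matrix$mat)), 1e-3)

  # masked empty bins are reported
  m <- matrix(3, 5, 5); m[2, ] <- 0; m[, 2] <- 0
  bm <- ice_balance(contact_matrix(m))
  expect_equal(bm$masked, 1L)
})

test_that("significant-interaction p-values match the binomial oracle", {
  cfg <- synth_config(seed = 33, hic_bins = 40, cid_blocks = NULL,
                      diff_contacts = data.frame(bin_i = 5L, bin_j = 20L,
                                                 boost = 20))
  h <- gen_hic_pair(cfg)
  bal <- ice_balance(h$test)
  sig <- call_significant(h$test, bal$matrix)
  N <- sum(h$test$mat[upper.tri(h$test$mat)])
  for (r in sample(nrow(sig), 25)) {
    p_pair <- sig$expected[r] / N
    expect_equal(sig$p[r],
                 binom_upper_oracle(sig$count[r], N, p_pair),
                 tolerance = 1e-10)
  }
  # the planted 20x spike is called
  spike <- sig[sig$bin_i == 5 & sig$bin_j == 20, ]
  expect_true(spike$significant)
})

test_that("the raw-count filter vetoes low-count pairs regardless of p", {
  sig <- data.frame(bin_i = 0L, bin_j = 5L, count = 2L, expected = 1e-6,
                    p = 1e-12, q = 1e-10)
  sig$significant <- sig$p < 0.01 & sig$q < 0.01 & sig$count > 2
  expect_false(sig$significant)
  # same construction through call_significant on a tiny crafted matrix
  m <- matrix(0L, 30, 30)
  for (d in 1:15) for (i in 1:30) {
    j <- (i + d - 1) %% 30 + 1
    m[i, j] <- 4L; m[j, i] <- 4L
  }
  m[1, 16] <- 2L; m[16, 1] <- 2L   # rare but under the count floor
  cm <- contact_matrix(m)
  sig2 <- call_significant(cm, contact_matrix(m, balanced = TRUE))
  row <- sig2[sig2$bin_i == 0 & sig2$bin_j == 15, ]
  expect_false(row$significant)
})

test_that("a flat decay matrix yields no significant calls", {
  cfg <- synth_config(seed = 34, hic_bins = 400, cid_blocks = NULL,
                      diff_contacts = NULL)
  h <- gen_hic_pair(cfg)
  bal <- ice_balance(h$ref)
  sig <- call_significant(h$ref, bal$matrix)
  expect_lte(sum(sig$significant), 1L)
})

test_that("insulation is flat on constant maps and dips at block junctions", {
  const <- contact_matrix(matrix(7, 40, 40), balanced = TRUE)
  prof <- insulation_profile(const, w = 5)
  expect_true(all(abs(prof$norm) < 1e-12))

  # two 50-bin blocks: within 10, between 1
  n <- 100
  block <- rep(1:2, each = 50)
  M <- outer(block, block, function(a, b) ifelse(a == b, 10, 1))
  diag(M) <- 10
  prof2 <- insulation_profile(contact_matrix(M, balanced = TRUE), w = 10)
  mins <- order(prof2$norm)[1:4]
  junctions <- c(0, 50) + 1  # bins 0 and 50 (1-based 1 and 51)
  expect_true(all(vapply(junctions, function(j)
    any(bin_distance(mins - 1, j - 1, n) <= 1), TRUE)))

  expect_error(insulation_profile(const, w = 1), ">= 2")
})

test_that("insulation and CID calls are rotation invariant", {
  cfg <- synth_config(seed = 36, hic_bins = 120,
                      cid_blocks = data.frame(start_bin = c(0L, 60L),
                                              end_bin = c(60L, 120L),
                                              within_boost = 4),
                      diff_contacts = NULL)
  h <- gen_hic_pair(cfg)
  bal <- ice_balance(h$ref)$matrix
  n <- 120; r <- 37
  perm <- ((0:(n - 1) + r) %% n) + 1
  rot <- contact_matrix(bal$mat[perm, perm], balanced = TRUE)
  p1 <- insulation_profile(bal, w = 10)
  p2 <- insulation_profile(rot, w = 10)
  expect_equal(p2$norm, p1$norm[perm], tolerance = 1e-10)
})

test_that("CID boundaries are recovered and CIDs tile the circle", {
  cfg <- synth_config(seed = 37, hic_bins = 150,
                      cid_blocks = data.frame(start_bin = c(0L, 70L),
                                              end_bin = c(70L, 150L),
                                              within_boost = 3),
                      diff_contacts = NULL)
  h <- gen_hic_pair(cfg)
  prof <- insulation_profile(ice_balance(h$ref)$matrix, w = 10)
  res <- call_cids(prof)
  expect_equal(nrow(res$boundaries), 2L)
  for (truth in c(0, 70)) {
    expect_lte(min(bin_distance(res$boundaries$bin, truth, 150)), 2)
  }
  lens <- vapply(seq_len(nrow(res$cids)), function(k) {
    s <- res$cids$start_bin[k]; e <- res$cids$end_bin[k]
    if (e > s) e - s else 150 - s + e
  }, 0)
  expect_equal(sum(lens), 150)

  # flat profile: one whole-circle CID
  flatp <- insulation_profile(contact_matrix(matrix(3, 60, 60),
                                             balanced = TRUE), w = 5)
  flat <- call_cids(flatp)
  expect_equal(nrow(flat$cids), 1L)
  expect_equal(flat$cids$end_bin - flat$cids$start_bin, 60)
})

test_that("unique elements follow the membership and overlap rules", {
  sig_a <- data.frame(bin_i = c(1L, 2L), bin_j = c(5L, 8L),
                      count = 5L, expected = 1, p = 1e-5, q = 1e-4,
                      significant = TRUE)
  sig_b <- sig_a[2, ]
  ue <- unique_elements(sig_a, sig_b)
  expect_equal(nrow(ue$interactions_unique_a), 1L)
  expect_equal(ue$interactions_unique_a$bin_i, 1L)
  expect_equal(nrow(ue$interactions_unique_b), 0L)

  cids <- data.frame(start_bin = c(0L, 100L), end_bin = c(100L, 200L))
  same <- unique_elements(sig_a, sig_a, cids, cids, n_bins = 200)
  expect_equal(nrow(same$cids_unique_a), 0L)

  # [0,100) vs [0,98): overlap 98/100 >= 0.8 on both sides -> matched
  cids_b <- data.frame(start_bin = c(0L, 98L), end_bin = c(98L, 200L))
  ov <- unique_elements(sig_a, sig_a, cids, cids_b, n_bins = 200)
  expect_equal(nrow(ov$cids_unique_a), 0L)
  # a genuinely displaced CID is unique
  cids_c <- data.frame(start_bin = c(0L, 50L), end_bin = c(50L, 200L))
  un <- unique_elements(sig_a, sig_a, cids, cids_c, n_bins = 200)
  expect_equal(nrow(un$cids_unique_a), 2L)
})

test_that("unique insulation regions flag discordant windows only", {
  mkprof <- function(x) structure(list(norm = x, n_bins = length(x),
                                       score = 2^x, w = 10L),
                                  class = "insulation_profile")
  set.seed(38)
  x <- stats::rnorm(100)
  expect_equal(nrow(unique_insulation_regions(mkprof(x), mkprof(x))), 0L)

  anti <- unique_insulation_regions(mkprof(x), mkprof(-x))
  expect_equal(nrow(anti), 1L)
  expect_equal(anti$start_bin, anti$end_bin)  # whole circle

  # boundary shifted by 5 bins on two-block data: regions cover the shifted
  # junction and nothing else
  n <- 100
  blockA <- rep(1:2, c(50, 50)); blockB <- rep(1:2, c(55, 45))
  mk <- function(block) {
    M <- outer(block, block, function(a, b) ifelse(a == b, 10, 1))
    diag(M) <- 10
    insulation_profile(contact_matrix(M, balanced = TRUE), w = 4)
  }
  reg <- unique_insulation_regions(mk(blockA), mk(blockB),
                                   window_bins = 15)
  expect_gt(nrow(reg), 0)
  covered <- unlist(lapply(seq_len(nrow(reg)), function(k) {
    s <- reg$start_bin[k]; e <- reg$end_bin[k]
    if (e > s) s:(e - 1) else c(s:(n - 1), seq_len(e) - 1)
  }))
  expect_true(any(bin_distance(covered, 50, n) <= 2))
  expect_true(any(bin_distance(covered, 55, n) <= 2))
  # the untouched junction at bin 0 stays concordant
  expect_false(any(bin_distance(covered, 0, n) <= 2))
})

test_that("genes are matched to region spans once each", {
  ann <- make_annotation(20000,
                         starts = c(11500L, 12000L, 15000L),
                         ends = c(11800L, 12500L, 15500L))
  regions <- data.frame(start_bin = 10L, end_bin = 12L)
  ids <- genes_in_regions(regions, bin_size = 1000, ann)
  expect_equal(ids, "g001")  # [12000,12500) excluded by half-open span

  two <- data.frame(start_bin = c(10L, 11L), end_bin = c(12L, 13L))
  ids2 <- genes_in_regions(two, bin_size = 1000, ann)
  expect_equal(sum(ids2 == "g001"), 1L)  # deduplicated
})
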