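test_that("genome generation is deterministic and exact in length", {
  cfg <- synth_config(seed = 11, genome_length = 20000)
  g1 <- gen_genome(cfg)
  g2 <- gen_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1$seq), 20000L)
})

test_that("order-0 base composition matches the configured probabilities", {
  cfg <- synth_config(seed = 3, genome_length = 100000,
                      base_probs = c(A = 0.25, C = 0.25, G = 0.25,
                                     T = 0.25))
  g <- gen_genome(cfg)
  freq <- table(strsplit(g$seq, "")[[1]]) / 100000
  # binomial 6 sigma: sqrt(0.25*0.75/1e5) * 6 ~ 0.008
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("first-order chains respect their transition matrix", {
  trans <- matrix(c(0.7, 0.1, 0.1, 0.1,
                    0.1, 0.7, 0.1, 0.1,
                    0.1, 0.1, 0.7, 0.1,
                    0.1, 0.1, 0.1, 0.7), 4, 4, byrow = TRUE)
  cfg <- synth_config(seed = 5, genome_length = 50000, markov_order = 1,
                      transition_probs = trans)
  g <- gen_genome(cfg)
  m <- train_markov(g$seq, order = 1, pseudocount = 0)
  expect_true(max(abs(m$trans - trans)) < 0.02)
})

test_that("generated genes are non-overlapping with the requested coverage", {
  cfg <- synth_config(seed = 21)
  ann <- gen_annotation(cfg)
  g <- ann$genes
  expect_equal(nrow(g), 100L)
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  # coverage sits near the configured expectation within +-5 points
  # (100 genes x mean 1000 bp / 200 kb = 50%)
  expect_lt(abs(sum(g$end - g$start) / cfg$genome_length - 0.5), 0.05)

  empty <- gen_annotation(synth_config(seed = 1, n_genes = 0))
  expect_equal(nrow(empty$genes), 0L)
  expect_equal(intergenic_intervals(empty),
               data.frame(start = 0L, end = 200000L))
})

test_that("zero planting rates leave the genome untouched", {
  cfg <- synth_config(seed = 2, genome_length = 30000, n_genes = 15,
                      rate_cds = 0, rate_ig = 0)
  g <- gen_genome(cfg)
  ann <- gen_annotation(cfg)
  pl <- plant_methylation(cfg, g, ann)
  expect_identical(pl$genome$seq, g$seq)
  expect_equal(nrow(pl$calls), 0L)
  expect_equal(nrow(pl$truth), 0L)
})

test_that("every planted instance is recovered by the occurrence scanner", {
  cfg <- synth_config(seed = 8, genome_length = 50000, n_genes = 25)
  pl <- plant_methylation(cfg, gen_genome(cfg), gen_annotation(cfg))
  occ <- find_motif_occurrences(pl$genome$seq, cfg$motif)
  key_occ <- paste(occ$start, occ$strand)
  key_truth <- paste(pl$truth$start, pl$truth$strand)
  expect_true(all(key_truth %in% key_occ))
  # and the emitted call positions are motif adenines inside the instance
  expect_true(all(pl$calls$position >= 0 &
                    pl$calls$position < cfg$genome_length))
})

test_that("planted class counts follow the configured Poisson densities", {
  cfg <- synth_config(seed = 31, rate_cds = 1.2, rate_ig = 0.6,
                      meth_fraction = 1)
  ann <- gen_annotation(cfg)
  pl <- plant_methylation(cfg, gen_genome(cfg), ann)
  cds_kb <- sum(ann$genes$end - ann$genes$start) / 1000
  ig_kb <- cfg$genome_length / 1000 - cds_kb
  n_cds <- sum(pl$truth$class == "CDS")
  n_ig <- sum(pl$truth$class == "IG")
  expect_lt(abs(n_cds - 1.2 * cds_kb), 4 * sqrt(1.2 * cds_kb))
  expect_lt(abs(n_ig - 0.6 * ig_kb), 4 * sqrt(0.6 * ig_kb))
})

test_that("contact pair generation is reproducible and symmetric", {
  cfg <- synth_config(seed = 13, hic_bins = 60,
                      cid_blocks = NULL, diff_contacts = NULL)
  h1 <- gen_hic_pair(cfg)
  h2 <- gen_hic_pair(cfg)
  expect_identical(h1$ref$mat, h2$ref$mat)
  # no blocks, no differential contacts: the two conditions coincide
  expect_identical(h1$ref$mat, h1$test$mat)
  expect_true(all(h1$ref$mat == floor(h1$ref$mat)))
  expect_true(all(h1$ref$mat >= 0))
  expect_identical(h1$ref$mat, t(h1$ref$mat))
})

test_that("distance decay of generated contacts recovers the exponent", {
  cfg <- synth_config(seed = 17, hic_bins = 500, decay_exponent = 1,
                      hic_scale = 50, cid_blocks = NULL,
                      diff_contacts = NULL)
  h <- gen_hic_pair(cfg)
  M <- h$ref$mat
  n <- 500
  d <- outer(0:(n - 1), 0:(n - 1), function(i, j) bin_distance(i, j, n))
  ut <- upper.tri(M)
  means <- tapply(M[ut], d[ut], mean)
  dd <- as.numeric(names(means))
  keep <- dd >= 1 & dd <= 100 & means > 0
  fit <- stats::lm(log(means[keep]) ~ log(dd[keep]))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.1)
})

test_that("differential boosts perturb only the planted pairs", {
  base <- list(seed = 19, hic_bins = 80, cid_blocks = NULL)
  cfg <- do.call(synth_config, c(base, list(
    diff_contacts = data.frame(bin_i = 10L, bin_j = 40L, boost = 12))))
  h <- gen_hic_pair(cfg)
  delta <- h$test$mat != h$ref$mat
  changed <- which(delta & upper.tri(delta, diag = TRUE), arr.ind = TRUE)
  expect_equal(nrow(changed), 1L)
  expect_equal(unname(changed[1, ]), c(11L, 41L))
  expect_gt(h$test$mat[11, 41], h$ref$mat[11, 41])
})

test_that("differential tables honour flags and planted odds structure", {
  ann <- make_enrich_annotation()
  cfg <- synth_config(seed = 4, de_frac = 0)
  de <- gen_de_table(cfg, ann)
  expect_equal(length(de$truth$de_ids), 0L)
  expect_true(all(de$table$padj > 0.05))

  cfg2 <- synth_config(seed = 4, de_frac = 0.05, enrichment_odds = 8)
  de2 <- gen_de_table(cfg2, ann)
  flagged <- filter_differential(de2$table, fc_threshold = 2, use = "padj")
  expect_setequal(c(flagged$up, flagged$down), de2$truth$de_ids)
})

test_that("emitted files agree with the in-memory truth tables", {
  outdir <- withr::local_tempdir()
  cfg <- synth_config(seed = 23, genome_length = 40000, n_genes = 20,
                      hic_bins = 50,
                      cid_blocks = data.frame(start_bin = c(0L, 25L),
                                              end_bin = c(25L, 50L),
                                              within_boost = 3),
                      diff_contacts = data.frame(bin_i = 5L, bin_j = 20L,
                                                 boost = 12))
  sim <- simulate_all(cfg, outdir)
  genome <- read_fasta(sim$paths$fasta)
  expect_identical(genome$seq, sim$genome$seq)
  ann <- read_gff3(sim$paths$gff, cfg$genome_length)
  expect_equal(ann$genes$start, sim$annotation$genes$start)
  expect_equal(ann$genes$cog, sim$annotation$genes$cog)
  calls <- read_methylation(sim$paths$mods, "mods_gff")
  expect_equal(calls$position, sim$calls$position)
  expect_equal(calls$strand, sim$calls$strand)
  ref <- bin_contacts(read_contacts(sim$paths$ref_contacts), cfg$hic_bins)
  expect_equal(ref$mat, sim$hic$ref$mat)
  truth <- jsonlite::read_json(sim$paths$truth, simplifyVector = TRUE)
  expect_equal(sort(truth$de$de_ids), sort(sim$de$truth$de_ids))
  expect_equal(truth$hic$boundaries_ref, sim$hic$truth$boundaries_ref)
})
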