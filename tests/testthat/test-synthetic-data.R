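# synthetic-data generator: determinism, ground-truth invariants, planted
# structure

test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(n_genes = 25, seed = 5)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(simulate_peaks(g1$genes, g1$truth, cfg),
                   simulate_peaks(g2$genes, g2$truth, cfg))
  expect_identical(simulate_expression(g1$genes, g1$truth, cfg),
                   simulate_expression(g2$genes, g2$truth, cfg))
  g3 <- simulate_genome(simulation_config(n_genes = 25, seed = 6))
  expect_false(identical(g1$promoters, g3$promoters))
})

test_that("ground-truth label constraints hold across random configs", {
  withr::local_seed(55)
  for (rep in 1:8) {
    cfg <- simulation_config(n_genes = sample(10:60, 1),
                             frac_bound = runif(1), frac_hre = runif(1),
                             frac_responsive = runif(1),
                             seed = sample(1e4, 1))
    tr <- simulate_genome(cfg)$truth
    expect_true(all(!tr$responsive | (tr$bound & tr$has_hre)))
    expect_true(all(!tr$has_hre | tr$bound))
    expect_equal(sum(tr$bound), round(cfg$frac_bound * cfg$n_genes))
  }
})

test_that("gene models fit their slots and promoters match window lengths", {
  cfg <- simulation_config(n_genes = 30, seed = 2)
  gen <- simulate_genome(cfg)
  expect_true(all(gen$genes$end <= cfg$chrom_length))
  expect_true(all(nchar(gen$promoters) == 2000))
  ov <- merge_peaks(gene = gen$genes)
  expect_equal(nrow(ov), nrow(gen$genes))   # non-overlapping gene bodies
  expect_error(simulation_config(n_genes = 1000, chrom_length = 60000,
                                 n_chroms = 1), "sizing")
})

test_that("planted HREs are present iff has_hre; gc 0 removes chance hits", {
  cfg <- simulation_config(n_genes = 30, gc_content = 0, seed = 8)
  gen <- simulate_genome(cfg)
  hre_count <- vapply(gen$promoters, function(s)
    nrow(scan_motif(s, hre_motif())), 0L)
  # in an A/T-only background every hit is a planted one
  expect_equal(unname(hre_count > 0), gen$truth$has_hre)
  expect_true(all(hre_count[gen$truth$has_hre] == 1L))

  cfg0 <- simulation_config(n_genes = 30, frac_hre = 0, gc_content = 0,
                            seed = 8)
  gen0 <- simulate_genome(cfg0)
  expect_equal(sum(vapply(gen0$promoters, function(s)
    nrow(scan_motif(s, hre_motif())), 0L)), 0L)
})

test_that("peak counts and decoy scores follow the config", {
  cfg <- simulation_config(n_genes = 20, frac_bound = 1, n_decoys = 0,
                           seed = 4)
  gen <- simulate_genome(cfg)
  pk <- simulate_peaks(gen$genes, gen$truth, cfg)
  expect_equal(nrow(pk), 20L)
  cfg2 <- simulation_config(n_genes = 20, frac_bound = 0.5, n_decoys = 30,
                            score_decoy_mean = 10, score_decoy_sd = 0,
                            seed = 4)
  gen2 <- simulate_genome(cfg2)
  pk2 <- simulate_peaks(gen2$genes, gen2$truth, cfg2)
  kept <- filter_definitive_peaks(pk2)
  expect_equal(nrow(pk2), 10L + 30L)
  expect_false(any(grepl("decoy", kept$name)))  # all decoys filtered at >20
})

test_that("noise-free expression plants the exact effect", {
  cfg <- simulation_config(n_genes = 30, noise_sd = 0, effect_log2fc = 2,
                           seed = 6)
  gen <- simulate_genome(cfg)
  em <- simulate_expression(gen$genes, gen$truth, cfg)
  s <- em$samples
  wt24 <- rowMeans(em$values[, s$genotype == "WT" & s$condition == "LPS" &
                               s$timepoint_h == 24, drop = FALSE])
  ko24 <- rowMeans(em$values[, s$genotype == "KO" & s$condition == "LPS" &
                               s$timepoint_h == 24, drop = FALSE])
  diff <- wt24 - ko24
  expect_equal(unname(diff[gen$truth$responsive]),
               rep(2, sum(gen$truth$responsive)))
  expect_equal(unname(diff[!gen$truth$responsive]),
               rep(0, sum(!gen$truth$responsive)))
  # frac_responsive = 0 and no noise -> WT and KO identical
  cfg0 <- simulation_config(n_genes = 10, noise_sd = 0, frac_responsive = 0,
                            seed = 6)
  gen0 <- simulate_genome(cfg0)
  em0 <- simulate_expression(gen0$genes, gen0$truth, cfg0)
  s0 <- em0$samples
  expect_equal(unname(em0$values[, s0$genotype == "WT"]),
               unname(em0$values[, s0$genotype == "KO"]))
})

test_that("simulated counts round-trip through counts_to_log2_tpm", {
  cfg <- simulation_config(n_genes = 40, noise_sd = 0.1, seed = 14)
  gen <- simulate_genome(cfg)
  em <- simulate_expression(gen$genes, gen$truth, cfg)
  len <- setNames(gen$genes$end - gen$genes$start, gen$genes$gene_id)
  cm <- simulate_counts(em, len, lib_size = 5e6, dispersion = 1000, seed = 1)
  expect_equal(cm$scale, "counts")
  back <- counts_to_log2_tpm(cm, len)
  # high depth + low dispersion: recovered log2 TPM correlates strongly
  expect_gt(cor(as.numeric(back$values), as.numeric(em$values)), 0.95)
})

test_that("simulate_dataset writes files that read back identically", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_genes = 15, seed = 10)
  out <- simulate_dataset(cfg, dir)
  genes <- read_gff3_genes(out$paths$genes)
  expect_equal(genes[order(genes$gene_id), ]$start, out$genes$start)
  proms <- read_fasta(out$paths$promoters)
  expect_identical(proms[names(out$promoters)], out$promoters)
  pk <- read_bed(out$paths$peaks, condition = "LPS", timepoint_h = 24)
  expect_equal(pk[, c("chrom", "start", "end", "score")],
               out$peaks[, c("chrom", "start", "end", "score")],
               ignore_attr = TRUE)
  expect_equal(read_tsv_matrix(out$paths$expression), out$expression$values)
  expect_equal(read_sample_meta(out$paths$samples), out$expression$samples,
               ignore_attr = TRUE)
})
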