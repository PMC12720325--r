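# peak filtering, merging, annotation, nearest-TSS assignment, selection

mk_peaks <- function(start, end, chrom = "chr1", score = 50)
  peak_table(rep(chrom, length(start)), start, end, score = score)

test_that("filter_definitive_peaks uses a strict >20 rule", {
  pk <- mk_peaks(c(0, 100, 200), c(50, 150, 250), score = c(20, 20.5, 100))
  expect_equal(nrow(filter_definitive_peaks(pk)), 2L)
  expect_equal(filter_definitive_peaks(pk)$score, c(20.5, 100))
  expect_equal(nrow(filter_definitive_peaks(mk_peaks(integer(), integer()))), 0L)
  pk21 <- mk_peaks(c(0, 100), c(50, 150), score = 21)
  expect_equal(nrow(filter_definitive_peaks(pk21)), 2L)
})

test_that("merge_peaks unions overlaps, keeps book-ended apart, is transitive", {
  m <- merge_peaks(mk_peaks(c(100, 150), c(200, 250)))
  expect_equal(m[, c("start", "end")], data.frame(start = 100L, end = 250L))

  m <- merge_peaks(mk_peaks(c(100, 200), c(200, 300)))
  expect_equal(nrow(m), 2L)   # book-ended intervals are NOT merged

  # transitive closure, checked against brute-force pairwise merging
  m <- merge_peaks(mk_peaks(c(0, 5, 15), c(10, 20, 30)))
  expect_equal(m[, c("start", "end")], data.frame(start = 0L, end = 30L))
})

test_that("merge_peaks is idempotent and order-insensitive", {
  withr::local_seed(33)
  for (rep in 1:20) {
    st <- sample(0:500, 15)
    pk <- mk_peaks(st, st + sample(5:80, 15, replace = TRUE))
    m1 <- merge_peaks(pk)
    m2 <- merge_peaks(peak_table(m1$chrom, m1$start, m1$end))
    expect_equal(m2[, c("chrom", "start", "end")],
                 m1[, c("chrom", "start", "end")])
    perm <- pk[sample(nrow(pk)), ]
    expect_equal(merge_peaks(perm)[, c("start", "end")],
                 m1[, c("start", "end")])
  }
})

test_that("count_set_overlap implements merged-interval Venn logic", {
  a <- mk_peaks(0, 100)
  expect_equal(count_set_overlap(a, a), list(a_only = 0L, b_only = 0L,
                                             shared = 1L))
  a <- mk_peaks(c(0, 1000), c(100, 1100))
  b <- mk_peaks(c(5000, 6000, 7000), c(5100, 6100, 7100))
  expect_equal(count_set_overlap(a, b), list(a_only = 2L, b_only = 3L,
                                             shared = 0L))
  a <- mk_peaks(0, 100)
  b <- mk_peaks(c(50, 200), c(150, 300))
  expect_equal(count_set_overlap(a, b), list(a_only = 0L, b_only = 1L,
                                             shared = 1L))
})

test_that("promoter windows are strand-aware mirrors about the TSS", {
  g <- gene_table(c("p", "m"), "chr1", c(10000, 8000), c(12000, 10001),
                  c("+", "-"))
  w <- promoter_windows(g)
  expect_equal(w$start[1], 8500L)    # + strand tss = 10000
  expect_equal(w$end[1], 10500L)
  expect_equal(w$start[2], 9501L)    # - strand tss = 10000, mirrored
  expect_equal(w$end[2], 11501L)

  # mirror-image oracle: in transcription orientation the window covers
  # 1500 bp upstream and 500 bp from the TSS on; for the - gene that means
  # genomic positions tss+1 .. tss+1500 upstream and tss-499 .. tss downstream
  tss <- 10000
  up_positions <- (tss + 1):(tss + 1500)
  dn_positions <- (tss - 499):tss
  expect_true(all(up_positions >= w$start[2] & up_positions < w$end[2]))
  expect_true(all(dn_positions >= w$start[2] & dn_positions < w$end[2]))
  expect_equal(w$end[2] - w$start[2], 2000L)

  g0 <- gene_table("edge", "chr1", 1000, 3000, "+")
  w0 <- promoter_windows(g0)
  expect_equal(c(w0$start, w0$end), c(0L, 1500L))  # clipped at 0
})

test_that("genomic categories are exhaustive with promoter > exon priority", {
  g <- gene_table("gA", "chr1", 10000, 14000, "+",
                  exons = data.frame(gene_id = "gA", start = 10000,
                                     end = 11000))
  # midpoint 10250 is in both the promoter window [8500,10500) and the exon
  pk <- mk_peaks(10200, 10300)
  expect_equal(as.character(classify_genomic_category(pk, g)), "promoter")
  # midpoint in exon, outside window
  pk <- mk_peaks(10700, 10900)
  expect_equal(as.character(classify_genomic_category(pk, g)), "exon")
  # gene-free chromosome
  pk <- mk_peaks(100, 200, chrom = "chr9")
  expect_equal(as.character(classify_genomic_category(pk, g)),
               "intron_or_intergenic")
  # every peak gets exactly one category; fractions sum to 1
  withr::local_seed(44)
  pk <- mk_peaks(sample(0:20000, 50), sample(0:20000, 50) + 21000)
  cat <- classify_genomic_category(pk, g)
  expect_false(anyNA(cat))
  expect_equal(sum(genomic_distribution_summary(pk, g)), 1, tolerance = 1e-12)
  expect_error(genomic_distribution_summary(mk_peaks(integer(), integer()), g),
               "no peaks")
})

test_that("nearest-gene assignment signs distance by transcription orientation", {
  g <- gene_table(c("geneA", "geneB"), "chr1", c(900, 1200), c(1100, 1400),
                  c("+", "+"))
  pk <- mk_peaks(995, 1005)   # midpoint 1000
  a <- assign_peak_to_nearest_gene(pk, g)
  expect_equal(a$gene_id, "geneA")
  expect_equal(a$distance, 100)

  # equidistant -> lexicographically smallest gene_id
  g <- gene_table(c("geneB", "geneA"), "chr1", c(900, 1100), c(1000, 1200),
                  c("+", "+"))
  pk <- mk_peaks(995, 1005)   # midpoint 1000, both TSS 100 away
  expect_equal(assign_peak_to_nearest_gene(pk, g)$gene_id, "geneA")

  # 500 bp 5' of a minus-strand TSS: midpoint > tss genomically
  g <- gene_table("gM", "chr1", 5000, 10001, "-")   # tss = 10000
  pk <- mk_peaks(10495, 10505)                      # midpoint 10500
  a <- assign_peak_to_nearest_gene(pk, g)
  expect_equal(a$distance, -500)
  pk <- mk_peaks(9495, 9505)                        # midpoint 9500, 3' side
  expect_equal(assign_peak_to_nearest_gene(pk, g)$distance, 500)
})

test_that("promoter-HRE selection requires the three-way intersection", {
  g <- gene_table("gA", "chr1", 10000, 12000, "+")
  win <- promoter_windows(g)            # [8500, 10500)
  seqlen <- win$end - win$start
  base <- paste(rep("A", seqlen), collapse = "")
  # plant an HRE at window offset 1500 (genomic 10000)
  with_hre <- base
  substr(with_hre, 1501, 1505) <- "ACGTG"
  proms <- c(gA = with_hre)
  pk_on <- mk_peaks(9900, 10100)       # covers the HRE
  pk_off <- mk_peaks(9000, 9500)       # in window but off the HRE
  pk_far <- mk_peaks(20000, 20200)     # 10 kb away
  expect_equal(select_promoter_hre_bound_genes(pk_on, g, proms), "gA")
  expect_equal(select_promoter_hre_bound_genes(pk_off, g, proms), character(0))
  expect_equal(select_promoter_hre_bound_genes(pk_far, g, proms), character(0))
  # no HRE in window -> never selected
  expect_equal(select_promoter_hre_bound_genes(pk_on, g, c(gA = base)),
               character(0))
  # relaxed mode: peak-in-window AND hit-in-window independently
  expect_equal(select_promoter_hre_bound_genes(pk_off, g, proms,
                                               strict = FALSE), "gA")
  # sequence length inconsistent with the window -> error
  expect_error(select_promoter_hre_bound_genes(pk_on, g, c(gA = "ACGTG")),
               "inconsistent")
})

test_that("selection recovers bound & has_hre exactly on clean synthetic data", {
  cfg <- simulation_config(n_genes = 40, noise_sd = 0, seed = 9)
  gen <- simulate_genome(cfg)
  peaks <- filter_definitive_peaks(simulate_peaks(gen$genes, gen$truth, cfg))
  sel <- select_promoter_hre_bound_genes(peaks, gen$genes, gen$promoters)
  expect_equal(sel, sort(gen$truth$gene_id[gen$truth$bound & gen$truth$has_hre]))
})
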