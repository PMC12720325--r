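# Ward clustering, dendrogram cuts, separation statistic, permutation tests

test_that("separation statistic matches the pairwise enumeration fixtures", {
  d <- as.matrix(dist(c(0, 0, 10, 10)))
  expect_equal(separation_statistic(d, c("A", "A", "B", "B")), 10)
  d0 <- as.matrix(dist(c(3, 3, 3, 3)))
  expect_equal(separation_statistic(d0, c("A", "A", "B", "B")), 0)
  # between mean (10+11+9+10)/4 = 10, within mean 1
  d <- as.matrix(dist(c(0, 1, 10, 11)))
  expect_equal(separation_statistic(d, c(1, 1, 2, 2)), 9)
  expect_error(separation_statistic(d, c(1, 1, 1, 1)), "2 clusters")
  expect_error(separation_statistic(as.matrix(dist(c(0, 5))), c(1, 2)),
               "singleton")
})

test_that("separation statistic is invariant to relabeling and reordering", {
  withr::local_seed(12)
  x <- matrix(rnorm(30), 10, 3)
  d <- as.matrix(dist(x))
  lab <- sample(c("A", "B", "C"), 10, replace = TRUE)
  while (length(unique(lab)) < 3) lab <- sample(c("A", "B", "C"), 10, TRUE)
  s0 <- separation_statistic(d, lab)
  relab <- c(A = "x", B = "y", C = "z")[lab]
  expect_equal(separation_statistic(d, relab), s0)
  perm <- sample(10)
  expect_equal(separation_statistic(d[perm, perm], lab[perm]), s0)
})

test_that("ward_d / ward_d2 dendrograms equal the naive Lance-Williams oracle", {
  withr::local_seed(21)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    m <- matrix(rnorm(n * 3), n, 3)
    rownames(m) <- paste0("g", seq_len(n))
    for (variant in c("ward_d", "ward_d2")) {
      hc <- hierarchical_cluster(m, cluster_config(linkage = variant))
      oracle <- oracle_ward(m, variant)
      expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
      for (step in seq_len(n - 1)) {
        got <- canon_partition(stats::cutree(hc, k = n - step))
        expect_equal(got, canon_partition(oracle$partitions[[step]]))
      }
    }
  }
})

test_that("dendrogram cutting covers the trivial and planted-blob cases", {
  m <- rbind(a = c(0, 0), b = c(0, 0.1), c = c(10, 10), d = c(10, 10.2))
  hc <- hierarchical_cluster(m)
  expect_equal(max(cut_dendrogram(hc, height = 1e9)$labels), 1L)
  expect_equal(max(cut_dendrogram(hc, height = 1e-6)$labels), 4L)
  cut2 <- cut_dendrogram(hc, k = 2)
  expect_equal(cut2$labels[1:2][1], cut2$labels[2])
  expect_equal(cut2$labels[3], cut2$labels[4])
  expect_true(cut2$labels[1] != cut2$labels[3])
  expect_equal(cut2$level, "subdivided")
  expect_error(cut_dendrogram(hc), "exactly one")
  expect_error(cut_dendrogram(hc, height = 1, k = 2), "exactly one")
  expect_error(hierarchical_cluster(rbind(c(1, NA), c(2, 3))), "drop_na_rows")
  # identical rows merge at height 0
  expect_equal(hierarchical_cluster(rbind(c(1, 1), c(1, 1)))$height, 0)
})

test_that("permutation test is deterministic and exact on degenerate data", {
  d <- as.matrix(dist(rep(0, 6)))
  res <- permutation_test(d, c(1, 1, 1, 2, 2, 2), n_permutations = 99,
                          seed = 4)
  expect_equal(res$p_value, 1)   # every permuted stat equals observed
  d2 <- as.matrix(dist(c(0, 1, 10, 11)))
  r1 <- permutation_test(d2, c(1, 1, 2, 2), seed = 11)
  r2 <- permutation_test(d2, c(1, 1, 2, 2), seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$n_permutations, 999L)
  expect_equal(r1$p_value, r1$n_at_least_as_extreme / 999)
  r3 <- permutation_test(d2, c(1, 1, 2, 2), seed = 11, add_one = TRUE)
  expect_equal(r3$p_value, (r3$n_at_least_as_extreme + 1) / 1000)
})

test_that("exhaustive test enumerates all size-preserving arrangements", {
  d <- as.matrix(dist(c(0, 1, 10, 11)))
  res <- exhaustive_permutation_test(d, c(1, 1, 2, 2))
  expect_equal(res$n_permutations, 6L)       # C(4,2)
  expect_equal(res$n_at_least_as_extreme, 2L) # observed + mirror split
  expect_equal(res$p_value, 1 / 3)
  expect_error(exhaustive_permutation_test(as.matrix(dist(c(0, 5))),
                                           c(1, 2)), "singleton")
  # unique strict maximum up to label swap -> p = 2 / C(6,3) = 0.1
  d6 <- as.matrix(dist(c(0, 0.5, 1, 20, 20.5, 21)))
  res6 <- exhaustive_permutation_test(d6, c(1, 1, 1, 2, 2, 2))
  expect_equal(res6$p_value, 2 / choose(6, 3))
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  d <- as.matrix(dist(c(0, 1, 10, 11)))
  mc <- permutation_test(d, c(1, 1, 2, 2), n_permutations = 4999, seed = 8)
  p <- 1 / 3
  expect_lt(abs(mc$p_value - p), 3 * sqrt(p * (1 - p) / 4999))
})

test_that("cluster mean profiles average by cluster x design cell", {
  cfg <- simulation_config(n_genes = 30, noise_sd = 0, effect_log2fc = 2,
                           seed = 13)
  gen <- simulate_genome(cfg)
  em <- simulate_expression(gen$genes, gen$truth, cfg)
  truth_cl <- ifelse(gen$truth$responsive, 1L, 2L)
  asg <- structure(list(item_ids = gen$truth$gene_id, labels = truth_cl,
                        level = "primary"), class = "cluster_assignment")
  prof <- cluster_mean_profiles(em, asg)
  # responsive cluster, WT LPS 24 h sits effect_log2fc above its baseline
  p1 <- prof[prof$cluster == 1, ]
  wt24 <- p1$mean_value[p1$genotype == "WT" & p1$condition == "LPS" &
                          p1$timepoint_h == 24]
  wt0 <- p1$mean_value[p1$genotype == "WT" & p1$condition == "LPS" &
                         p1$timepoint_h == 0]
  expect_equal(wt24 - wt0, 2)
  # single-gene cluster reproduces its own trajectory
  one <- structure(list(item_ids = gen$truth$gene_id[1], labels = 1L,
                        level = "primary"), class = "cluster_assignment")
  pr1 <- cluster_mean_profiles(em, one)
  cell <- em$samples$genotype == "WT" & em$samples$condition == "LPS" &
    em$samples$timepoint_h == 0
  expect_equal(pr1$mean_value[pr1$genotype == "WT" & pr1$condition == "LPS" &
                                pr1$timepoint_h == 0],
               mean(em$values[1, cell]))
})
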