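# Synthetic data with planted ground truth: toy gene models, promoter
# sequences with planted RCGTG motifs, condition/timepoint-structured peak
# sets for WT and KO, and log2-TPM expression time courses with planted
# bound-and-responsive vs bound-but-unresponsive gene groups.
#
# Gene layout: each gene occupies a fixed 6000-bp slot; the gene body is
# slot + [2000, 4000) so the -1500/+500 promoter window of either strand and
# a decoy-peak gap both fit inside the slot.

.SLOT_BP <- 6000L
.GENE_OFFSET <- 2000L
.GENE_LEN <- 2000L

#' Derive a per-stage seed from a global seed
#'
#' Deterministic, stage-name-hashed, and kept below 2^31 so it is a valid R
#' integer seed. Rerunning a single stage with the derived seed reproduces
#' its output from a full run.
#'
#' @param seed global integer seed.
#' @param stage stage name string.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483563)
}

#' Simulation configuration
#'
#' Defaults state the emulated world: a WT/KO x {LPS, hypoxia} x {0,4,24 h}
#' design with 3 replicates, half the genes bound, 80% of bound promoters
#' carrying a planted HRE, half of those responsive with a +2 log2
#' fold-change, definitive peak scores ~ N(60, 15) vs sub-threshold decoys
#' ~ N(10, 3), and 45% GC background sequence.
#'
#' @param n_genes number of genes.
#' @param chrom_length,n_chroms toy genome geometry (each gene needs a
#'   6000-bp slot).
#' @param frac_bound fraction of genes given a promoter peak.
#' @param frac_hre fraction of bound genes with a planted RCGTG under the
#'   peak.
#' @param frac_responsive fraction of bound-HRE genes planted as responsive.
#' @param effect_log2fc planted log2 fold-change for responsive genes (WT at
#'   the induced timepoint vs baseline and vs KO); > 0.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param gc_content background base composition.
#' @param score_bound_mean,score_bound_sd,score_decoy_mean,score_decoy_sd
#'   peak score distributions (decoys sit below the >20 filter).
#' @param n_decoys number of sub-threshold intergenic decoy peaks.
#' @param peak_width bp width of planted peaks (centered on the TSS).
#' @param n_replicates replicates per genotype x condition x timepoint.
#' @param baseline_mean,baseline_sd per-gene baseline log2-TPM distribution.
#' @param seed RNG seed; all generators are pure functions of (config, seed).
#' @export
simulation_config <- function(n_genes = 200L, chrom_length = 1000000L,
                              n_chroms = 2L, frac_bound = 0.5,
                              frac_hre = 0.8, frac_responsive = 0.5,
                              effect_log2fc = 2, noise_sd = 0.25,
                              gc_content = 0.45,
                              score_bound_mean = 60, score_bound_sd = 15,
                              score_decoy_mean = 10, score_decoy_sd = 3,
                              n_decoys = 50L, peak_width = 200L,
                              n_replicates = 3L,
                              baseline_mean = 6, baseline_sd = 1.5,
                              seed = 1L) {
  fr <- c(frac_bound, frac_hre, frac_responsive)
  stopifnot(all(fr >= 0), all(fr <= 1), effect_log2fc > 0, noise_sd >= 0,
            gc_content >= 0, gc_content <= 1, peak_width > 0,
            n_replicates >= 1)
  capacity <- as.integer(floor(chrom_length / .SLOT_BP)) * n_chroms
  if (n_genes > capacity)
    stop("sizing error: ", n_genes, " genes do not fit (capacity ", capacity,
         ")", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 chrom_length = as.integer(chrom_length),
                 n_chroms = as.integer(n_chroms), frac_bound = frac_bound,
                 frac_hre = frac_hre, frac_responsive = frac_responsive,
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 gc_content = gc_content,
                 score_bound_mean = score_bound_mean,
                 score_bound_sd = score_bound_sd,
                 score_decoy_mean = score_decoy_mean,
                 score_decoy_sd = score_decoy_sd,
                 n_decoys = as.integer(n_decoys),
                 peak_width = as.integer(peak_width),
                 n_replicates = as.integer(n_replicates),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# planted peak interval for a gene (centered on the TSS)
.planted_peak_interval <- function(gene, peak_width) {
  half <- peak_width %/% 2L
  c(gene$tss - half, gene$tss - half + peak_width)
}

# remove every RCGTG occurrence (either strand) whose genomic interval
# intersects [ps, pe), by mutating the hit's middle base; seq is the + strand
# window sequence starting at genomic position wstart
.scrub_hre <- function(seq, wstart, ps, pe) {
  mot <- hre_motif()
  for (iter in 1:100) {
    hits <- scan_motif(seq, mot, both_strands = TRUE)
    hs <- wstart + hits$start
    he <- wstart + hits$end
    bad <- which(hs < pe & he > ps)
    if (!length(bad)) return(seq)
    i <- hits$start[bad[1]] + 3L  # 1-based index of the hit's middle base
    substr(seq, i, i) <- sample(c("A", "T"), 1)
  }
  warning("could not scrub all motif occurrences from a peak footprint")
  seq
}

#' Simulate a toy genome: gene models, promoter sequences, ground truth
#'
#' Lays out non-overlapping genes in fixed slots over `n_chroms`
#' chromosomes, draws ground-truth labels (bound, has_hre, responsive with
#' responsive => bound & has_hre), and generates each gene's promoter-window
#' sequence i.i.d. at `gc_content`. For bound genes, chance RCGTG
#' occurrences under the future peak footprint are scrubbed; for has_hre
#' genes exactly one RCGTG (R uniform in {A,G}, strand uniform) is planted at
#' the peak center, rejection-resampling up to 100 times if flanks recreate
#' a second overlapping occurrence. Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @param window a [promoter_window_config()] (sequence coordinates follow
#'   it).
#' @return list(genes, promoters, truth): a [gene_table()], a named vector
#'   of + strand window sequences, and a data.frame (gene_id, bound,
#'   has_hre, responsive, cluster) where cluster is 1 = responsive,
#'   2 = bound HRE unresponsive, 0 = background.
#' @export
simulate_genome <- function(config, window = promoter_window_config()) {
  withr::with_seed(derive_seed(config$seed, "genome"), {
    n <- config$n_genes
    per_chrom <- as.integer(floor(config$chrom_length / .SLOT_BP))
    chrom_i <- ((seq_len(n) - 1L) %/% per_chrom) + 1L
    slot_i <- ((seq_len(n) - 1L) %% per_chrom)
    slot0 <- slot_i * .SLOT_BP
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gene_id <- sprintf("gene%03d", seq_len(n))
    genes <- gene_table(gene_id, chrom = paste0("chr", chrom_i),
                        start = slot0 + .GENE_OFFSET,
                        end = slot0 + .GENE_OFFSET + .GENE_LEN,
                        strand = strand)
    n_bound <- round(config$frac_bound * n)
    bound_idx <- sort(sample(n, n_bound))
    n_hre <- round(config$frac_hre * n_bound)
    hre_idx <- sort(sample(bound_idx, n_hre))
    n_resp <- round(config$frac_responsive * n_hre)
    resp_idx <- if (n_hre) sort(sample(hre_idx, n_resp)) else integer()
    truth <- data.frame(gene_id = gene_id,
                        bound = seq_len(n) %in% bound_idx,
                        has_hre = seq_len(n) %in% hre_idx,
                        responsive = seq_len(n) %in% resp_idx,
                        stringsAsFactors = FALSE)
    truth$cluster <- ifelse(truth$responsive, 1L,
                            ifelse(truth$bound & truth$has_hre, 2L, 0L))
    win <- promoter_windows(genes, window)
    wlen <- win$end - win$start
    proms <- character(n)
    for (i in seq_len(n)) {
      s <- .random_seq(wlen[i], config$gc_content)
      if (truth$bound[i]) {
        pk <- .planted_peak_interval(genes[i, ], config$peak_width)
        s <- .scrub_hre(s, win$start[i], pk[1], pk[2])
        if (truth$has_hre[i]) {
          mot_len <- 5L
          rel_center <- genes$tss[i] - win$start[i] - mot_len %/% 2L
          for (attempt in 1:100) {
            core <- paste0(sample(c("A", "G"), 1), "CGTG")
            if (sample(c(TRUE, FALSE), 1)) core <- revcomp(core)
            s2 <- s
            substr(s2, rel_center + 1L, rel_center + mot_len) <- core
            hits <- scan_motif(s2, hre_motif(), both_strands = TRUE)
            hs <- win$start[i] + hits$start
            he <- win$start[i] + hits$end
            if (sum(hs < pk[2] & he > pk[1]) == 1L) break
          }
          if (attempt == 100L)
            warning("planting created extra motif occurrences for ",
                    gene_id[i])
          s <- s2
        }
      }
      proms[i] <- s
    }
    names(proms) <- gene_id
    list(genes = genes, promoters = proms, truth = truth)
  })
}

#' Simulate peak sets
#'
#' Every bound gene gets one WT peak of width `peak_width` centered on its
#' TSS with score ~ N(score_bound_mean, score_bound_sd) floored at 0, stamped
#' condition = LPS, timepoint 24 h. `n_decoys` sub-threshold decoy peaks are
#' placed in intergenic slot gaps with scores ~ N(score_decoy_mean,
#' score_decoy_sd) floored at 0. The KO genotype gets no true peaks (an
#' empty KO peak table plays the role of the knockout control).
#'
#' @param genes,truth output of [simulate_genome()].
#' @param config a [simulation_config()].
#' @return a [peak_table()].
#' @export
simulate_peaks <- function(genes, truth, config) {
  withr::with_seed(derive_seed(config$seed, "peaks"), {
    bi <- which(truth$bound)
    tabs <- list()
    if (length(bi)) {
      half <- config$peak_width %/% 2L
      tabs$bound <- peak_table(
        chrom = genes$chrom[bi], start = genes$tss[bi] - half,
        end = genes$tss[bi] - half + config$peak_width,
        name = paste0("pk_", genes$gene_id[bi]),
        score = pmax(0, stats::rnorm(length(bi), config$score_bound_mean,
                                     config$score_bound_sd)),
        condition = "LPS", timepoint_h = 24, genotype = "WT")
    }
    if (config$n_decoys > 0) {
      per_chrom <- as.integer(floor(config$chrom_length / .SLOT_BP))
      chrom <- paste0("chr", sample(config$n_chroms, config$n_decoys,
                                    replace = TRUE))
      slot0 <- (sample(per_chrom, config$n_decoys, replace = TRUE) - 1L) *
        .SLOT_BP
      start <- slot0 + 5600L  # inside the intergenic slot gap [5500, 6000)
      tabs$decoy <- peak_table(
        chrom = chrom, start = start, end = start + 200L,
        name = sprintf("decoy_%d", seq_len(config$n_decoys)),
        score = pmax(0, stats::rnorm(config$n_decoys, config$score_decoy_mean,
                                     config$score_decoy_sd)),
        condition = "LPS", timepoint_h = 24, genotype = "WT")
    }
    out <- do.call(rbind, tabs)
    if (is.null(out)) out <- peak_table(character(), integer(), integer())
    rownames(out) <- NULL
    class(out) <- c("peak_table", "data.frame")
    out
  })
}

#' Simulate a log2-TPM expression time course
#'
#' Samples cover {WT, KO} x {LPS, hypoxia} x {0, 4, 24 h} x replicates.
#' Each gene has baseline log2 expression ~ N(baseline_mean, baseline_sd).
#' Responsive genes gain `effect_log2fc` in WT at the induced timepoint
#' (24 h under LPS, 4 h under hypoxia) while KO stays at baseline;
#' unresponsive bound genes follow identical WT and KO trajectories.
#' Additive N(0, noise_sd) noise throughout.
#'
#' @inheritParams simulate_peaks
#' @return an `expr_matrix` with scale "log2tpm".
#' @export
simulate_expression <- function(genes, truth, config) {
  withr::with_seed(derive_seed(config$seed, "expression"), {
    design <- expand.grid(replicate = seq_len(config$n_replicates),
                          timepoint_h = c(0, 4, 24),
                          condition = c("LPS", "hypoxia"),
                          genotype = c("WT", "KO"),
                          stringsAsFactors = FALSE)
    design <- design[, c("genotype", "condition", "timepoint_h", "replicate")]
    sm <- sample_meta(
      sample_id = sprintf("%s_%s_%gh_r%d", design$genotype, design$condition,
                          design$timepoint_h, design$replicate),
      genotype = design$genotype, condition = design$condition,
      timepoint_h = design$timepoint_h, replicate = design$replicate)
    n <- nrow(genes)
    base <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    vals <- matrix(base, nrow = n, ncol = nrow(sm))
    induced <- (sm$genotype == "WT") &
      ((sm$condition == "LPS" & sm$timepoint_h == 24) |
         (sm$condition == "hypoxia" & sm$timepoint_h == 4))
    vals[truth$responsive, induced] <- vals[truth$responsive, induced] +
      config$effect_log2fc
    if (config$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), 0, config$noise_sd),
                            nrow = n)
    dimnames(vals) <- list(genes$gene_id, sm$sample_id)
    expr_matrix(vals, sm, "log2tpm")
  })
}

#' Simulate a read-count matrix from a log2-TPM matrix
#'
#' Exercises [counts_to_log2_tpm()]: expected counts are proportional to
#' TPM x gene length within each sample, scaled to `lib_size`, with
#' Negative Binomial sampling at the given dispersion (size parameter).
#'
#' @param em `expr_matrix` on the log2tpm scale.
#' @param gene_lengths named vector of gene lengths (bp).
#' @param lib_size expected total counts per sample.
#' @param dispersion NB size parameter (larger = less overdispersed).
#' @param seed RNG seed.
#' @return `expr_matrix` with scale "counts".
#' @export
simulate_counts <- function(em, gene_lengths, lib_size = 2e6,
                            dispersion = 50, seed = 1L) {
  stopifnot(em$scale == "log2tpm")
  withr::with_seed(derive_seed(seed, "counts"), {
    tpm <- 2^em$values - 1
    tpm[tpm < 0] <- 0
    len_kb <- gene_lengths[rownames(em$values)] / 1000
    w <- tpm * len_kb
    mu <- sweep(w, 2, colSums(w), "/") * lib_size
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    expr_matrix(counts, em$samples, "counts")
  })
}

#' Simulate a full dataset and write it to disk
#'
#' Writes genes.gff3, promoters.fasta, peaks.bed, expression.tsv,
#' samples.tsv and truth.tsv under `dir` (the formats [read_gff3_genes()],
#' [read_fasta()], [read_bed()], [read_tsv_matrix()] and
#' [read_sample_meta()] read back).
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param window a [promoter_window_config()].
#' @return (invisibly) list(genes, promoters, truth, peaks, expression,
#'   paths).
#' @export
simulate_dataset <- function(config, dir,
                             window = promoter_window_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(config, window)
  peaks <- simulate_peaks(gen$genes, gen$truth, config)
  em <- simulate_expression(gen$genes, gen$truth, config)
  paths <- list(genes = file.path(dir, "genes.gff3"),
                promoters = file.path(dir, "promoters.fasta"),
                peaks = file.path(dir, "peaks.bed"),
                expression = file.path(dir, "expression.tsv"),
                samples = file.path(dir, "samples.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_gff3_genes(gen$genes, paths$genes)
  write_fasta(gen$promoters, paths$promoters)
  write_bed(peaks, paths$peaks)
  write_tsv_matrix(em$values, paths$expression)
  write_sample_meta(em$samples, paths$samples)
  utils::write.table(gen$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(genes = gen$genes, promoters = gen$promoters,
                 truth = gen$truth, peaks = peaks, expression = em,
                 paths = paths))
}
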