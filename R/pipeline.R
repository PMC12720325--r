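# End-to-end orchestration: simulate (or load) -> score-filter -> merge ->
# annotate/assign -> select promoter-HRE genes -> expression filter cascade ->
# two-level Ward clustering -> permutation test -> dependence classification
# -> motif enrichment. One manifest records the funnel.

#' Pipeline configuration
#'
#' Either `simulate = TRUE` (inputs generated from `sim`) or explicit input
#' paths for genes (GFF3), promoters (FASTA), peaks (BED), expression (TSV)
#' and samples (TSV). Stage seeds are derived from the global seed by stage
#' name hashing, so individual stages are reproducible in isolation.
#'
#' @param out_dir output directory.
#' @param simulate generate inputs with the synthetic-data module.
#' @param sim a [simulation_config()] (used when `simulate`).
#' @param paths named list of input paths (used when `simulate = FALSE`):
#'   genes, promoters, peaks, expression, samples.
#' @param peak_filter a [peak_filter_config()].
#' @param window a [promoter_window_config()].
#' @param filters a [filter_config()].
#' @param clustering a [cluster_config()].
#' @param background a [background_spec()].
#' @param motifs motif panel for enrichment (default: HRE plus a decoy-free
#'   panel of just the HRE).
#' @param n_permutations permutations for the cluster-separation test.
#' @param seed global seed, recorded in the manifest.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE,
                            sim = simulation_config(),
                            paths = NULL,
                            peak_filter = peak_filter_config(),
                            window = promoter_window_config(),
                            filters = filter_config(),
                            clustering = cluster_config(),
                            background = background_spec(),
                            motifs = list(hre_motif()),
                            n_permutations = 999L, seed = 1L) {
  structure(list(out_dir = out_dir, simulate = isTRUE(simulate), sim = sim,
                 paths = paths, peak_filter = peak_filter, window = window,
                 filters = filters, clustering = clustering,
                 background = background, motifs = motifs,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.validate_pipeline_config <- function(config) {
  if (!config$simulate) {
    need <- c("genes", "promoters", "peaks", "expression", "samples")
    if (is.null(config$paths) || !all(need %in% names(config$paths)))
      stop("pipeline config: paths must name ", paste(need, collapse = ", "),
           call. = FALSE)
    missing <- !vapply(config$paths[need], file.exists, TRUE)
    if (any(missing))
      stop("pipeline config: missing input file(s): ",
           paste(unlist(config$paths[need][missing]), collapse = ", "),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages execute in a fixed order; every stage's outputs are written under
#' `out_dir` before the next stage starts, and the manifest records
#' per-stage record counts (the funnel) plus the permutation-test p-value.
#'
#' @param config a [pipeline_config()].
#' @return list(manifest, selected_genes, classification, clustering,
#'   permutation, enrichment, truth) — `truth` is NULL when running on real
#'   inputs.
#' @export
run_pipeline <- function(config) {
  .validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message(sprintf("[%s] %s", stage,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  truth <- NULL
  if (config$simulate) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, "simulate")
    data <- simulate_dataset(sim, file.path(config$out_dir, "input"),
                             config$window)
    genes <- data$genes; promoters <- data$promoters
    peaks <- data$peaks; em <- data$expression; truth <- data$truth
    note("simulate", n_genes = nrow(genes), n_peaks = nrow(peaks),
         n_samples = nrow(em$samples))
  } else {
    genes <- read_gff3_genes(config$paths$genes)
    promoters <- read_fasta(config$paths$promoters)
    peaks <- read_bed(config$paths$peaks)
    em <- expr_matrix(read_tsv_matrix(config$paths$expression),
                      read_sample_meta(config$paths$samples), "log2tpm")
    note("load", n_genes = nrow(genes), n_peaks = nrow(peaks),
         n_samples = nrow(em$samples))
  }

  # ChIP side: definitive peaks, merged intervals, annotation, selection
  def_peaks <- filter_definitive_peaks(peaks, config$peak_filter)
  note("filter_peaks", n_in = nrow(peaks), n_definitive = nrow(def_peaks))
  merged <- merge_peaks(all = def_peaks)
  write_bed(merged, file.path(config$out_dir, "merged_peaks.bed"))
  note("merge_peaks", n_merged = nrow(merged))
  if (nrow(def_peaks)) {
    categ <- classify_genomic_category(def_peaks, genes, config$window)
    assign <- assign_peak_to_nearest_gene(def_peaks, genes)
    assign$category <- as.character(categ)
    utils::write.table(assign,
                       file.path(config$out_dir, "peak_gene_assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dist_summary <- genomic_distribution_summary(def_peaks, genes,
                                                 config$window)
    note("annotate", promoter = round(dist_summary[["promoter"]], 4),
         exon = round(dist_summary[["exon"]], 4),
         intron_or_intergenic = round(dist_summary[["intron_or_intergenic"]], 4))
  }
  selected <- select_promoter_hre_bound_genes(def_peaks, genes, promoters,
                                              hre_motif(), config$window)
  writeLines(selected, file.path(config$out_dir, "promoter_hre_genes.txt"))
  note("select_genes", n_selected = length(selected))

  # expression side: NA -> zero-SD -> induction filter cascade (fixed order)
  em2 <- drop_na_rows(em)
  em3 <- drop_zero_sd_rows(em2)
  induced <- filter_induced(em3, "LPS", config$filters)
  cluster_set <- intersect(selected, induced)
  note("expression_filters", n_after_na = nrow(em2$values),
       n_after_sd = nrow(em3$values), n_induced = length(induced),
       n_cluster_set = length(cluster_set))

  clustering <- NULL; permres <- NULL
  if (length(cluster_set) >= 2) {
    cm <- em3$values[cluster_set, , drop = FALSE]
    hc <- hierarchical_cluster(cm, config$clustering)
    primary <- cut_dendrogram(hc, height = config$clustering$first_cut_height)
    # second-level cut inside the largest primary cluster
    sizes <- table(primary$labels)
    big <- as.integer(names(sizes)[which.max(sizes)])
    sub_ids <- primary$item_ids[primary$labels == big]
    sub <- NULL
    if (length(sub_ids) >= config$clustering$subdivide_k) {
      hc2 <- hierarchical_cluster(cm[sub_ids, , drop = FALSE],
                                  config$clustering)
      sub <- cut_dendrogram(hc2, k = config$clustering$subdivide_k)
      d2 <- stats::dist(cm[sub_ids, , drop = FALSE])
      permres <- permutation_test(d2, sub$labels,
                                  n_permutations = config$n_permutations,
                                  seed = derive_seed(config$seed, "permtest"))
      jsonlite::write_json(unclass(permres),
                           file.path(config$out_dir, "permutation_test.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    out <- data.frame(gene_id = primary$item_ids,
                      primary_cluster = primary$labels,
                      subcluster = NA_integer_, stringsAsFactors = FALSE)
    if (!is.null(sub))
      out$subcluster[match(sub$item_ids, out$gene_id)] <- sub$labels
    utils::write.table(out, file.path(config$out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    clustering <- list(hclust = hc, primary = primary, subdivided = sub,
                       table = out)
    note("cluster", n_primary = length(unique(primary$labels)),
         p_value = if (!is.null(permres)) permres$p_value else NA)
  } else {
    note("cluster", skipped = "fewer than 2 genes in cluster set")
  }

  # dependence classification runs on the NA-filtered matrix: the zero-SD and
  # induction filters only shape the clustering table
  classification <- classify_hif_dependence(em2, selected, config$filters)
  utils::write.table(classification,
                     file.path(config$out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("classify", responsive = sum(classification$class == "responsive"),
       unresponsive = sum(classification$class == "unresponsive"),
       unbound = sum(classification$class == "unbound"))

  # enrichment: selected promoters vs GC/length-matched unselected promoters
  enrichment <- NULL
  pool <- promoters[setdiff(names(promoters), selected)]
  if (length(selected) && length(pool)) {
    bg_spec <- config$background
    bg_spec$seed <- derive_seed(config$seed, "background")
    bg <- sample_matched_background(promoters[selected], pool, bg_spec)
    enrichment <- run_known_motif_enrichment(promoters[selected], bg,
                                             config$motifs)
    utils::write.table(enrichment,
                       file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("enrich", top_motif = enrichment$motif_name[1],
         top_p = signif(enrichment$p_value[1], 3))
  }

  manifest$counts <- list(
    peaks_in = nrow(peaks), peaks_definitive = nrow(def_peaks),
    genes_selected = length(selected),
    genes_after_na = nrow(em2$values), genes_after_sd = nrow(em3$values),
    genes_induced = length(induced),
    genes_clustered = length(cluster_set))
  manifest$version <- as.character(utils::packageVersion("hrepipe"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(manifest = manifest, selected_genes = selected,
       classification = classification, clustering = clustering,
       permutation = permres, enrichment = enrichment, truth = truth)
}

#' Compare a pipeline classification against planted ground truth
#'
#' The truth class of a gene is responsive / unresponsive (bound with HRE) /
#' unbound (everything else, including bound genes without an HRE, which the
#' promoter-HRE selection deliberately excludes).
#'
#' @param classification output of [classify_hif_dependence()].
#' @param truth ground-truth data.frame from [simulate_genome()].
#' @return list(accuracy, n, confusion).
#' @export
classification_accuracy <- function(classification, truth) {
  want <- ifelse(truth$responsive, "responsive",
                 ifelse(truth$bound & truth$has_hre, "unresponsive",
                        "unbound"))
  got <- as.character(classification$class[
    match(truth$gene_id, classification$gene_id)])
  list(accuracy = mean(got == want), n = length(want),
       confusion = table(truth = want, predicted = got))
}
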