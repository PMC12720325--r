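# Peak filtering, merging, overlap counting, genomic-category annotation,
# nearest-TSS assignment and promoter-HRE gene selection: the ChIP side of
# the integration.

#' Peak score filter configuration
#'
#' Peaks with caller scores strictly greater than the threshold are treated
#' as definitive binding events; everything else is discarded before
#' integration.
#'
#' @param min_score_exclusive strict lower bound on scores (default 20).
#' @export
peak_filter_config <- function(min_score_exclusive = 20) {
  stopifnot(min_score_exclusive >= 0)
  structure(list(min_score_exclusive = min_score_exclusive),
            class = "peak_filter_config")
}

#' Promoter window configuration
#'
#' The promoter is the region from `upstream_bp` before to `downstream_bp`
#' after the transcription start site, in transcription orientation
#' (default -1500/+500 bp).
#'
#' @param upstream_bp,downstream_bp window extents in bp (window non-empty).
#' @export
promoter_window_config <- function(upstream_bp = 1500L, downstream_bp = 500L) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0,
            upstream_bp + downstream_bp > 0)
  structure(list(upstream_bp = as.integer(upstream_bp),
                 downstream_bp = as.integer(downstream_bp)),
            class = "promoter_window_config")
}

#' Keep definitive peaks (score strictly above threshold)
#'
#' @param peaks a [peak_table()].
#' @param config a [peak_filter_config()].
#' @return filtered peak table, input order preserved.
#' @export
filter_definitive_peaks <- function(peaks, config = peak_filter_config()) {
  out <- peaks[peaks$score > config$min_score_exclusive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge overlapping peaks across one or more peak sets
#'
#' Intervals sharing at least 1 bp of overlap on the same chromosome are
#' merged into their union (transitively). Book-ended intervals
#' (end == start) are NOT merged. Each merged interval records which input
#' sets contributed to it.
#'
#' @param ... peak tables (or interval data.frames with chrom/start/end),
#'   optionally named; unnamed sets are labelled set1, set2, ...
#' @return data.frame (chrom, start, end, sources, n_sources) where `sources`
#'   is a comma-separated sorted list of contributing set labels.
#' @export
merge_peaks <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  labels <- names(sets)
  if (is.null(labels)) labels <- rep("", length(sets))
  labels[!nzchar(labels)] <- sprintf("set%d", which(!nzchar(labels)))
  all_df <- do.call(rbind, lapply(seq_along(sets), function(i)
    data.frame(chrom = sets[[i]]$chrom, start = sets[[i]]$start,
               end = sets[[i]]$end, src = labels[i],
               stringsAsFactors = FALSE)))
  if (is.null(all_df) || !nrow(all_df))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      sources = character(), n_sources = integer(),
                      stringsAsFactors = FALSE))
  out <- lapply(split(all_df, all_df$chrom), function(d) {
    # 0-based half-open -> 1-based closed for IRanges; min.gapwidth = 0 keeps
    # book-ended intervals separate (gap 0 not bridged)
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    srcs <- vapply(S4Vectors::mcols(red)$revmap, function(idx)
      paste(sort(unique(d$src[idx])), collapse = ","), "")
    nsrc <- vapply(S4Vectors::mcols(red)$revmap, function(idx)
      length(unique(d$src[idx])), 1L)
    data.frame(chrom = d$chrom[1], start = IRanges::start(red) - 1L,
               end = IRanges::end(red), sources = srcs, n_sources = nsrc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count merged-interval overlap between two peak sets
#'
#' Venn-style counts computed on merged intervals: `shared` merged intervals
#' absorbed peaks from both sets; `a_only`/`b_only` from one.
#'
#' @param peaks_a,peaks_b peak tables.
#' @return list(a_only, b_only, shared).
#' @export
count_set_overlap <- function(peaks_a, peaks_b) {
  m <- merge_peaks(a = peaks_a, b = peaks_b)
  list(a_only = sum(m$sources == "a"),
       b_only = sum(m$sources == "b"),
       shared = sum(m$sources == "a,b"))
}

#' Strand-aware promoter windows for a gene table
#'
#' For `+` genes the window is `[tss - upstream, tss + downstream)`; for `-`
#' genes it is mirrored about the TSS base: `[tss - downstream + 1,
#' tss + upstream + 1)`, so the window always covers `upstream_bp` bases 5'
#' of the TSS and `downstream_bp` bases from the TSS onward in transcription
#' orientation (TSS base included on the downstream side). Windows are
#' clipped at position 0 and, when `chrom_lengths` is given, at chromosome
#' ends.
#'
#' @param genes a [gene_table()].
#' @param config a [promoter_window_config()].
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data.frame (gene_id, chrom, start, end, strand).
#' @export
promoter_windows <- function(genes, config = promoter_window_config(),
                             chrom_lengths = NULL) {
  up <- config$upstream_bp
  dn <- config$downstream_bp
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - up, genes$tss - dn + 1L)
  end <- ifelse(plus, genes$tss + dn, genes$tss + up + 1L)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    if (anyNA(lim)) stop("missing chromosome length", call. = FALSE)
    end <- pmin(end, as.integer(lim))
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, stringsAsFactors = FALSE)
}

.peak_midpoints <- function(peaks) as.integer(floor((peaks$start + peaks$end) / 2))

#' Classify peaks into promoter / exon / intron-or-intergenic
#'
#' The decision uses the peak midpoint, `floor((start + end) / 2)`, with
#' priority promoter > exon > intron_or_intergenic: a peak is `promoter` if
#' any gene's strand-aware promoter window contains the midpoint, else `exon`
#' if any exon contains it, else `intron_or_intergenic`. Every peak receives
#' exactly one category.
#'
#' @param peaks a [peak_table()].
#' @param genes a [gene_table()].
#' @param config a [promoter_window_config()].
#' @return factor with levels promoter, exon, intron_or_intergenic.
#' @export
classify_genomic_category <- function(peaks, genes,
                                      config = promoter_window_config()) {
  mids <- .peak_midpoints(peaks)
  win <- promoter_windows(genes, config)
  ex <- gene_exons(genes)
  echrom <- genes$chrom[match(ex$gene_id, genes$gene_id)]
  in_any <- function(chrom, pos, ichrom, istart, iend) {
    vapply(seq_along(pos), function(i)
      any(ichrom == chrom[i] & istart <= pos[i] & pos[i] < iend), TRUE)
  }
  in_prom <- in_any(peaks$chrom, mids, win$chrom, win$start, win$end)
  in_exon <- in_any(peaks$chrom, mids, echrom, ex$start, ex$end)
  cat <- ifelse(in_prom, "promoter",
                ifelse(in_exon, "exon", "intron_or_intergenic"))
  factor(cat, levels = c("promoter", "exon", "intron_or_intergenic"))
}

#' Fraction of peaks per genomic category
#'
#' @inheritParams classify_genomic_category
#' @return named numeric vector (promoter, exon, intron_or_intergenic)
#'   summing to 1.
#' @export
genomic_distribution_summary <- function(peaks, genes,
                                         config = promoter_window_config()) {
  if (!nrow(peaks)) stop("no peaks", call. = FALSE)
  tab <- table(classify_genomic_category(peaks, genes, config))
  as.numeric(tab) / nrow(peaks) -> frac
  stats::setNames(frac, names(tab))
}

#' Assign each peak to its nearest gene TSS
#'
#' Distance is peak midpoint minus TSS, with the sign flipped for `-` strand
#' genes so that positive always means downstream of the TSS in transcription
#' orientation. Nearest by absolute distance; ties broken by
#' lexicographically smallest gene_id.
#'
#' @param peaks a [peak_table()].
#' @param genes a [gene_table()] (non-empty).
#' @return data.frame (peak_name, gene_id, distance).
#' @export
assign_peak_to_nearest_gene <- function(peaks, genes) {
  if (!nrow(genes)) stop("no genes to assign to", call. = FALSE)
  mids <- .peak_midpoints(peaks)
  ord <- order(genes$gene_id)
  g <- genes[ord, , drop = FALSE]
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    same <- which(g$chrom == peaks$chrom[i])
    if (!length(same))
      return(data.frame(peak_name = peaks$name[i], gene_id = NA_character_,
                        distance = NA_real_, stringsAsFactors = FALSE))
    d <- mids[i] - g$tss[same]
    d <- ifelse(g$strand[same] == "-", -d, d)
    j <- same[which.min(abs(d))]  # g sorted by gene_id => lexicographic tie-break
    dj <- mids[i] - g$tss[j]
    if (g$strand[j] == "-") dj <- -dj
    data.frame(peak_name = peaks$name[i], gene_id = g$gene_id[j],
               distance = dj, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Select genes whose promoter HRE is covered by a peak
#'
#' A gene is selected iff there exists a peak and a motif hit such that the
#' peak interval intersects the hit interval and the hit lies inside the
#' gene's promoter window (a three-way intersection at the motif-hit level).
#' With `strict = FALSE` the weaker reading — peak overlapping the window and
#' a hit anywhere in the window, independently — is used instead.
#'
#' Promoter sequences must be the + strand genomic sequence of each gene's
#' promoter window (names = gene ids), so hit offsets map to genomic
#' coordinates by adding the window start.
#'
#' @param peaks score-filtered [peak_table()].
#' @param genes a [gene_table()].
#' @param promoter_seqs named character vector of window sequences.
#' @param mot motif to scan (default [hre_motif()]).
#' @param config a [promoter_window_config()].
#' @param both_strands scan both strands (default TRUE).
#' @param strict three-way intersection (default) vs independent containment.
#' @return sorted character vector of selected gene ids.
#' @export
select_promoter_hre_bound_genes <- function(peaks, genes, promoter_seqs,
                                            mot = hre_motif(),
                                            config = promoter_window_config(),
                                            both_strands = TRUE,
                                            strict = TRUE) {
  win <- promoter_windows(genes, config)
  sel <- character(0)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    s <- promoter_seqs[[gid]]
    if (is.null(s) || is.na(s)) next
    wlen <- win$end[i] - win$start[i]
    if (nchar(s) != wlen)
      stop("promoter sequence length for ", gid, " (", nchar(s),
           ") inconsistent with window (", wlen, ")", call. = FALSE)
    hits <- scan_motif(s, mot, both_strands, seq_name = gid)
    if (!nrow(hits)) next
    hs <- win$start[i] + hits$start
    he <- win$start[i] + hits$end
    pk <- peaks[peaks$chrom == win$chrom[i], , drop = FALSE]
    if (!nrow(pk)) next
    if (strict) {
      ok <- any(outer(pk$start, he, `<`) & outer(pk$end, hs, `>`))
    } else {
      peak_in_win <- any(pk$start < win$end[i] & pk$end > win$start[i])
      ok <- peak_in_win  # hits already known to exist inside the window
    }
    if (ok) sel <- c(sel, gid)
  }
  sort(unique(sel))
}
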