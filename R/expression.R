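# Count -> TPM transformation and the expression filter cascade and
# HIF-dependence classification.
#
# All fold thresholds are strict ("more than 1.2-fold", "more than twofold")
# and are evaluated on the linear scale via differences of mean log2 values:
# mean_log2(a) - mean_log2(b) > log2(ratio).

#' Expression filter configuration
#'
#' @param induction_ratio linear fold threshold for the 24 h vs 4 h induction
#'   filter (default 1.2, strict).
#' @param dependence_ratio linear WT-vs-KO fold threshold defining
#'   HIF-dependent (responsive) genes (default 2, strict).
#' @param require_positive_sd drop zero-variance rows before clustering.
#' @export
filter_config <- function(induction_ratio = 1.2, dependence_ratio = 2.0,
                          require_positive_sd = TRUE) {
  stopifnot(induction_ratio > 1, dependence_ratio > 1)
  structure(list(induction_ratio = induction_ratio,
                 dependence_ratio = dependence_ratio,
                 require_positive_sd = isTRUE(require_positive_sd)),
            class = "filter_config")
}

#' Convert a count matrix to log2 TPM
#'
#' Per sample: rate_g = count_g / length_kb_g; TPM_g = rate_g / sum(rate) *
#' 1e6; output is log2(TPM + pseudocount). TPM columns sum to 1e6 before the
#' log transform (relative error <= 1e-6), and the transform is invariant to
#' rescaling all counts of a sample by a constant.
#'
#' @param counts an `expr_matrix` with scale "counts", or a plain numeric
#'   matrix (then `samples` must be given).
#' @param gene_lengths named vector of gene lengths in bp (> 0), covering all
#'   rows.
#' @param pseudocount added on the TPM scale before log2 (default 1).
#' @param samples [sample_meta()] when `counts` is a bare matrix.
#' @return an `expr_matrix` with scale "log2tpm".
#' @export
counts_to_log2_tpm <- function(counts, gene_lengths, pseudocount = 1,
                               samples = NULL) {
  if (inherits(counts, "expr_matrix")) {
    stopifnot(counts$scale == "counts")
    samples <- counts$samples
    m <- counts$values
  } else {
    m <- as.matrix(counts)
    if (is.null(samples)) stop("samples metadata required", call. = FALSE)
  }
  len <- gene_lengths[rownames(m)]
  if (anyNA(len)) stop("gene_lengths missing for some genes", call. = FALSE)
  if (any(len <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (any(m < 0)) stop("counts must be >= 0", call. = FALSE)
  zero <- colSums(m) == 0
  if (any(zero))
    stop("all-zero sample column(s): ",
         paste(colnames(m)[zero], collapse = ","), call. = FALSE)
  rate <- m / (len / 1000)
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  expr_matrix(log2(tpm + pseudocount), samples, "log2tpm")
}

#' Remove rows containing missing values
#'
#' @param em an `expr_matrix` (or matrix).
#' @return same type, rows with any NA removed; count logged via message.
#' @export
drop_na_rows <- function(em) {
  v <- if (inherits(em, "expr_matrix")) em$values else em
  keep <- rowSums(is.na(v)) == 0
  dropped <- sum(!keep)
  if (dropped) message("drop_na_rows: removed ", dropped, " row(s)")
  if (!any(keep)) warning("all rows contained NA")
  out <- v[keep, , drop = FALSE]
  if (inherits(em, "expr_matrix")) expr_matrix(out, em$samples, em$scale) else out
}

#' Remove rows with exactly zero standard deviation
#'
#' The criterion is exact zero: any variation, however small, keeps the row.
#' Single-column matrices have SD 0 everywhere by convention, so all rows are
#' removed with a warning.
#'
#' @inheritParams drop_na_rows
#' @export
drop_zero_sd_rows <- function(em) {
  v <- if (inherits(em, "expr_matrix")) em$values else em
  sds <- if (ncol(v) < 2) rep(0, nrow(v)) else apply(v, 1, stats::sd)
  keep <- sds != 0
  if (ncol(v) < 2 && nrow(v)) warning("single-sample matrix: SD is 0 for every row")
  dropped <- sum(!keep)
  if (dropped) message("drop_zero_sd_rows: removed ", dropped, " row(s)")
  out <- v[keep, , drop = FALSE]
  if (inherits(em, "expr_matrix")) expr_matrix(out, em$samples, em$scale) else out
}

.mean_log2_by <- function(em, genotype, condition, timepoint) {
  s <- em$samples
  idx <- s$genotype == genotype & s$condition == condition &
    s$timepoint_h == timepoint
  if (!any(idx)) return(NULL)
  rowMeans(em$values[, idx, drop = FALSE])
}

#' Genes induced between 4 h and 24 h
#'
#' Keeps genes whose mean linear expression at 24 h exceeds
#' `induction_ratio` times the mean at 4 h, i.e.
#' mean_log2(24 h) - mean_log2(4 h) > log2(induction_ratio), strict.
#' Evaluated on WT samples of the given condition.
#'
#' @param em `expr_matrix` on the log2tpm scale.
#' @param condition stimulus to evaluate (default "LPS").
#' @param config a [filter_config()].
#' @return character vector of induced gene ids (input row order).
#' @export
filter_induced <- function(em, condition = "LPS", config = filter_config()) {
  stopifnot(em$scale == "log2tpm")
  m4 <- .mean_log2_by(em, "WT", condition, 4)
  m24 <- .mean_log2_by(em, "WT", condition, 24)
  if (is.null(m4) || is.null(m24))
    stop("WT samples at 4 h and 24 h required for condition ", condition,
         call. = FALSE)
  rownames(em$values)[(m24 - m4) > log2(config$induction_ratio)]
}

#' Classify bound genes as responsive / unresponsive / unbound
#'
#' A bound gene is `responsive` iff the WT/KO mean linear ratio exceeds
#' `dependence_ratio` (strictly) at at least one post-stimulus timepoint in
#' at least one of the given conditions; bound genes failing this are
#' `unresponsive`; genes not in `bound_genes` are `unbound`.
#'
#' @param em `expr_matrix` on the log2tpm scale with WT and KO samples.
#' @param bound_genes character vector of bound gene ids.
#' @param config a [filter_config()].
#' @param conditions conditions examined (default LPS and hypoxia).
#' @param timepoints post-stimulus timepoints examined (default 4 and 24 h;
#'   the comparison timepoint is a free choice, recorded here).
#' @return data.frame (gene_id, class, best_log2_ratio, best_condition,
#'   best_timepoint) over all genes in `em`.
#' @export
classify_hif_dependence <- function(em, bound_genes, config = filter_config(),
                                    conditions = c("LPS", "hypoxia"),
                                    timepoints = c(4, 24)) {
  stopifnot(em$scale == "log2tpm")
  gids <- rownames(em$values)
  best <- rep(-Inf, length(gids))
  best_cond <- rep(NA_character_, length(gids))
  best_tp <- rep(NA_real_, length(gids))
  for (cond in conditions) for (tp in timepoints) {
    wt <- .mean_log2_by(em, "WT", cond, tp)
    ko <- .mean_log2_by(em, "KO", cond, tp)
    if (is.null(wt) && is.null(ko)) next
    if (is.null(wt) || is.null(ko))
      stop("missing genotype for condition ", cond, " at ", tp, " h",
           call. = FALSE)
    r <- wt - ko
    upd <- r > best
    best[upd] <- r[upd]
    best_cond[upd] <- cond
    best_tp[upd] <- tp
  }
  if (all(!is.finite(best)))
    stop("no samples found for requested conditions/timepoints", call. = FALSE)
  bound <- gids %in% bound_genes
  cls <- ifelse(!bound, "unbound",
                ifelse(best > log2(config$dependence_ratio),
                       "responsive", "unresponsive"))
  data.frame(gene_id = gids,
             class = factor(cls, levels = c("responsive", "unresponsive",
                                            "unbound")),
             best_log2_ratio = best, best_condition = best_cond,
             best_timepoint = best_tp, stringsAsFactors = FALSE)
}

#' Stimulus-specific upregulated gene sets
#'
#' A gene is LPS-specific iff its WT mean linear expression at the induced
#' timepoint under LPS exceeds twice that under hypoxia AND WT exceeds KO
#' under LPS (both strict); symmetrically for hypoxia. The two sets are
#' disjoint by construction.
#'
#' @param em `expr_matrix` on the log2tpm scale.
#' @param config a [filter_config()]; the cross-stimulus threshold reuses
#'   `dependence_ratio`.
#' @param timepoint_lps,timepoint_hypoxia induced timepoints compared
#'   (defaults 24 h for LPS, 4 h for hypoxia).
#' @return list(lps_specific, hypoxia_specific) of gene id vectors.
#' @export
stimulus_specific_gene_sets <- function(em, config = filter_config(),
                                        timepoint_lps = 24,
                                        timepoint_hypoxia = 4) {
  stopifnot(em$scale == "log2tpm")
  thr <- log2(config$dependence_ratio)
  wt_l <- .mean_log2_by(em, "WT", "LPS", timepoint_lps)
  wt_h <- .mean_log2_by(em, "WT", "hypoxia", timepoint_hypoxia)
  ko_l <- .mean_log2_by(em, "KO", "LPS", timepoint_lps)
  ko_h <- .mean_log2_by(em, "KO", "hypoxia", timepoint_hypoxia)
  if (is.null(wt_l) || is.null(wt_h) || is.null(ko_l) || is.null(ko_h))
    stop("need WT and KO samples under both conditions", call. = FALSE)
  gids <- rownames(em$values)
  lps <- gids[(wt_l - wt_h) > thr & (wt_l - ko_l) > 0]
  hyp <- gids[(wt_h - wt_l) > thr & (wt_h - ko_h) > 0]
  list(lps_specific = lps, hypoxia_specific = hyp)
}
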