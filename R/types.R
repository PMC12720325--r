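#' @keywords internal
"_PACKAGE"

# All internal coordinates are 0-based half-open [start, end); conversions to
# 1-based conventions happen only at I/O boundaries (GFF3 shifted, BED native).

.valid_strands <- c("+", "-", "*")
.valid_conditions <- c("LPS", "hypoxia", "none")
.valid_genotypes <- c("WT", "KO")

.check_intervals <- function(chrom, start, end, what = "interval") {
  if (any(is.na(chrom) | !nzchar(chrom)))
    stop(what, ": chrom must be non-empty", call. = FALSE)
  if (any(start != floor(start)) || any(end != floor(end)))
    stop(what, ": coordinates must be integers", call. = FALSE)
  if (any(start < 0)) stop(what, ": start must be >= 0", call. = FALSE)
  if (any(start >= end))
    stop(what, ": start must be < end (0-based half-open)", call. = FALSE)
  invisible(TRUE)
}

#' Construct a validated peak table
#'
#' Peaks are located, scored binding events stamped with the experimental
#' condition, timepoint and genotype of the sample they were called in.
#' Coordinates are 0-based half-open, as in BED.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param name peak identifiers; autogenerated when `NULL`.
#' @param score non-negative peak-caller scores.
#' @param strand one of `"+"`, `"-"`, `"*"`.
#' @param condition stimulus: `"LPS"`, `"hypoxia"` or `"none"`.
#' @param timepoint_h hours after stimulus (non-negative).
#' @param genotype `"WT"` or `"KO"`.
#' @return a `data.frame` of class `peak_table`.
#' @export
peak_table <- function(chrom, start, end, name = NULL, score = 0,
                       strand = "*", condition = "none", timepoint_h = 0,
                       genotype = "WT") {
  n <- length(chrom)
  if (n == 0L) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     name = character(), score = numeric(),
                     strand = character(), condition = character(),
                     timepoint_h = numeric(), genotype = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("peak_table", "data.frame")
    return(df)
  }
  .check_intervals(chrom, start, end, "peak")
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   name = as.character(name),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   condition = rep_len(as.character(condition), n),
                   timepoint_h = rep_len(as.numeric(timepoint_h), n),
                   genotype = rep_len(as.character(genotype), n),
                   stringsAsFactors = FALSE)
  if (any(df$score < 0)) stop("peak: score must be >= 0", call. = FALSE)
  if (!all(df$strand %in% .valid_strands)) stop("peak: bad strand", call. = FALSE)
  if (!all(df$condition %in% .valid_conditions))
    stop("peak: condition must be one of ", paste(.valid_conditions, collapse = "/"),
         call. = FALSE)
  if (!all(df$genotype %in% .valid_genotypes))
    stop("peak: genotype must be WT or KO", call. = FALSE)
  if (any(df$timepoint_h < 0)) stop("peak: timepoint_h must be >= 0", call. = FALSE)
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Construct a validated gene-model table
#'
#' Each gene has a body interval, a strand, and exons carried in the `exons`
#' attribute (a data.frame with columns gene_id, start, end). The transcription
#' start site (TSS) is derived from the strand: the leftmost base for `+`
#' genes, the rightmost base (`end - 1`) for `-` genes.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom,start,end gene body (0-based half-open).
#' @param strand `"+"` or `"-"` per gene.
#' @param exons optional data.frame (gene_id, start, end) of exon intervals.
#' @return a `data.frame` of class `gene_table` with columns
#'   gene_id, chrom, start, end, strand, tss and an `exons` attribute.
#' @export
gene_table <- function(gene_id, chrom, start, end, strand, exons = NULL) {
  if (length(gene_id) == 0L) {
    df <- data.frame(gene_id = character(), chrom = character(),
                     start = integer(), end = integer(), strand = character(),
                     tss = integer(), stringsAsFactors = FALSE)
    attr(df, "exons") <- data.frame(gene_id = character(), start = integer(),
                                    end = integer(), stringsAsFactors = FALSE)
    class(df) <- c("gene_table", "data.frame")
    return(df)
  }
  .check_intervals(chrom, start, end, "gene")
  if (anyDuplicated(gene_id)) stop("duplicate gene_id", call. = FALSE)
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be + or -", call. = FALSE)
  tss <- ifelse(strand == "+", start, end - 1L)
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), tss = as.integer(tss),
                   stringsAsFactors = FALSE)
  if (is.null(exons)) {
    exons <- data.frame(gene_id = df$gene_id, start = df$start, end = df$end,
                        stringsAsFactors = FALSE)
  }
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "start", "end") %in% names(exons)))
  if (nrow(exons)) {
    .check_intervals(rep("x", nrow(exons)), exons$start, exons$end, "exon")
    idx <- match(exons$gene_id, df$gene_id)
    if (anyNA(idx)) stop("exon with unknown gene_id", call. = FALSE)
    if (any(exons$start < df$start[idx]) || any(exons$end > df$end[idx]))
      stop("exon outside gene body", call. = FALSE)
    ord <- order(exons$gene_id, exons$start)
    exons <- exons[ord, , drop = FALSE]
    ov <- exons$gene_id[-1] == exons$gene_id[-nrow(exons)] &
      exons$start[-1] < exons$end[-nrow(exons)]
    if (nrow(exons) > 1 && any(ov))
      stop("overlapping exons within a gene", call. = FALSE)
    rownames(exons) <- NULL
  }
  attr(df, "exons") <- exons
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Exons of a gene table
#' @param genes a `gene_table`.
#' @return data.frame (gene_id, start, end), sorted.
#' @export
gene_exons <- function(genes) attr(genes, "exons")

#' Construct sample metadata
#'
#' Encodes the experimental design: genotype (wild-type vs knockout),
#' stimulus, timepoint in hours and replicate number for each sample column
#' of an expression matrix.
#'
#' @param sample_id unique sample identifiers.
#' @param genotype,condition,timepoint_h,replicate per-sample design fields.
#' @return data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, genotype, condition, timepoint_h,
                        replicate = 1L) {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id", call. = FALSE)
  df <- data.frame(sample_id = as.character(sample_id),
                   genotype = rep_len(as.character(genotype), n),
                   condition = rep_len(as.character(condition), n),
                   timepoint_h = rep_len(as.numeric(timepoint_h), n),
                   replicate = rep_len(as.integer(replicate), n),
                   stringsAsFactors = FALSE)
  if (!all(df$genotype %in% .valid_genotypes)) stop("bad genotype", call. = FALSE)
  if (!all(df$condition %in% .valid_conditions)) stop("bad condition", call. = FALSE)
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Construct an expression matrix with sample metadata
#'
#' A gene-by-sample numeric matrix with its measurement scale recorded
#' explicitly so downstream fold-change filters know whether values are raw
#' counts, TPM, or log2(TPM + pseudocount).
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param samples a [sample_meta()] data.frame matching the columns.
#' @param scale one of `"counts"`, `"tpm"`, `"log2tpm"`.
#' @return object of class `expr_matrix`: list(values, samples, scale).
#' @export
expr_matrix <- function(values, samples, scale = c("log2tpm", "tpm", "counts")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values need gene rownames", call. = FALSE)
  if (anyDuplicated(rownames(values))) stop("duplicate gene_ids", call. = FALSE)
  if (!identical(colnames(values), samples$sample_id))
    stop("matrix colnames must equal samples$sample_id (same order)", call. = FALSE)
  if (scale == "counts") {
    v <- values[!is.na(values)]
    if (any(v < 0) || any(v != floor(v)))
      stop("counts scale requires non-negative integer values", call. = FALSE)
  }
  structure(list(values = values, samples = samples, scale = scale),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# subset an expr_matrix by gene ids and/or sample logical/index
.em_subset <- function(em, genes = NULL, samples = NULL) {
  v <- em$values
  s <- em$samples
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    s <- s[samples, , drop = FALSE]
  }
  expr_matrix(v, s, em$scale)
}
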