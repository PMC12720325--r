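# Readers/writers for the standard formats the pipeline touches.
# BED is natively 0-based half-open; GFF3 is 1-based inclusive and is shifted
# at this boundary only.

#' Read a BED3/BED6 file as a peak table
#'
#' Columns beyond the first three are optional: 4 = name, 5 = score,
#' 6 = strand. A missing score defaults to 0. Condition/timepoint/genotype
#' metadata are not part of BED; they default to none/0/WT and can be set by
#' the caller afterwards (or via a sidecar table).
#'
#' @param path BED file.
#' @param condition,timepoint_h,genotype metadata applied to every record.
#' @return a [peak_table()].
#' @export
read_bed <- function(path, condition = "none", timepoint_h = 0,
                     genotype = "WT") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(peak_table(character(), integer(), integer(),
                      condition = condition, timepoint_h = timepoint_h,
                      genotype = genotype))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error at line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 columns", call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1]],
         ": non-integer coordinates", call. = FALSE)
  bad <- start >= end | start < 0
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1]],
         ": requires 0 <= start < end", call. = FALSE)
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  name[is.na(name) | name == "."] <- sprintf("peak_%d", which(is.na(name) | name == "."))
  score <- rep(0, length(lines))
  has5 <- nf >= 5
  if (any(has5)) {
    raw <- vapply(fields[has5], `[[`, "", 5L)
    val <- suppressWarnings(as.numeric(ifelse(raw == ".", "0", raw)))
    if (anyNA(val))
      stop("BED parse error at line ", lineno[has5][which(is.na(val))[1]],
           ": non-numeric score", call. = FALSE)
    score[has5] <- val
  }
  strand <- rep("*", length(lines))
  has6 <- nf >= 6
  if (any(has6)) {
    s <- vapply(fields[has6], `[[`, "", 6L)
    strand[has6] <- ifelse(s %in% c("+", "-"), s, "*")
  }
  peak_table(chrom, start, end, name = name, score = score, strand = strand,
             condition = condition, timepoint_h = timepoint_h,
             genotype = genotype)
}

#' Write peaks (or any interval data.frame) as BED6
#'
#' @param peaks data.frame with chrom/start/end and optionally name, score,
#'   strand.
#' @param path output file.
#' @export
write_bed <- function(peaks, path) {
  n <- nrow(peaks)
  name <- if ("name" %in% names(peaks)) peaks$name else sprintf("peak_%d", seq_len(n))
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "*"
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", peaks$chrom, peaks$start,
                   peaks$end, name, format(score, trim = TRUE), strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models (gene + exon features) from GFF3
#'
#' GFF3 coordinates are 1-based inclusive; they are converted to the internal
#' 0-based half-open convention (start-1, end). Exons are grouped under their
#' parent gene via the Parent attribute (directly, or through an mRNA whose
#' Parent is a gene). Exons with no resolvable gene parent are skipped with a
#' warning.
#'
#' @param path GFF3 file.
#' @return a [gene_table()].
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (!nrow(df)) return(gene_table(character(), character(), integer(),
                                   integer(), character()))
  first_chr <- function(x) vapply(x, function(v)
    if (length(v)) as.character(v[[1]]) else NA_character_, "")
  ids <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA_character_, nrow(df))
  parents <- if ("Parent" %in% names(df)) first_chr(df$Parent) else rep(NA_character_, nrow(df))
  type <- as.character(df$type)
  is_gene <- type == "gene"
  gid <- ids[is_gene]
  gid[is.na(gid) | !nzchar(gid)] <- sprintf("gene_%d", which(is.na(gid) | !nzchar(gid)))
  # map transcript-level features to their gene parent
  tx2gene <- stats::setNames(parents, ids)[type %in% c("mRNA", "transcript")]
  resolve <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (p %in% gid) return(p)
    g <- unname(tx2gene[p])
    if (!is.na(g) && g %in% gid) g else NA_character_
  }
  is_exon <- type == "exon"
  exon_gene <- vapply(parents[is_exon], resolve, "")
  if (any(is.na(exon_gene)))
    warning(sum(is.na(exon_gene)), " exon(s) with no resolvable gene parent skipped")
  keep <- !is.na(exon_gene)
  exons <- data.frame(gene_id = exon_gene[keep],
                      start = df$start[is_exon][keep] - 1L,
                      end = df$end[is_exon][keep],
                      stringsAsFactors = FALSE)
  if (!nrow(exons)) exons <- NULL
  gene_table(gene_id = gid,
             chrom = as.character(df$seqnames)[is_gene],
             start = df$start[is_gene] - 1L, end = df$end[is_gene],
             strand = as.character(df$strand)[is_gene], exons = exons)
}

#' Write gene models as GFF3
#' @param genes a [gene_table()].
#' @param path output file.
#' @export
write_gff3_genes <- function(genes, path) {
  ex <- gene_exons(genes)
  glines <- sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    genes$chrom, genes$start + 1L, genes$end, genes$strand,
                    genes$gene_id)
  echrom <- genes$chrom[match(ex$gene_id, genes$gene_id)]
  estrand <- genes$strand[match(ex$gene_id, genes$gene_id)]
  elines <- sprintf("%s\t.\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                    echrom, ex$start + 1L, ex$end, estrand, ex$gene_id)
  writeLines(c("##gff-version 3", glines, elines), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are uppercased; IUPAC ambiguity letters other than A/C/G/T/N are
#' mapped to N with a warning, so downstream motif scanning sees the
#' restricted alphabet only.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1], call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  other <- gsub("[ACGTN]", "", seqs)
  if (any(nzchar(other))) {
    warning("non-ACGTN letters mapped to N in ", sum(nzchar(other)), " sequence(s)")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), "")
    names(seqs) <- nm
  }
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read/write a gene-by-sample matrix as TSV
#'
#' Layout: first column `gene_id`, header row = sample ids. Round trips are
#' exact for values representable at full double precision.
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_tsv_matrix
#' @param m numeric matrix (rownames = gene ids).
#' @export
write_tsv_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write sample metadata TSV
#'
#' Columns: sample_id, genotype, condition, timepoint_h, replicate.
#' @param path TSV file.
#' @return a [sample_meta()].
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_meta(df$sample_id, df$genotype, df$condition, df$timepoint_h,
              df$replicate)
}

#' @rdname read_sample_meta
#' @param samples a [sample_meta()].
#' @export
write_sample_meta <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
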