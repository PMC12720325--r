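# IUPAC consensus scanning. The hypoxia response element (HRE) core bound by
# HIF complexes is 5'-RCGTG-3' (R = A or G); scanning is implemented for the
# general one-letter ambiguity alphabet so decoy panels can be screened with
# the same machinery.

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), N = c("A", "C", "G", "T")
)

.iupac_comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", N = "N")

#' Define an IUPAC consensus motif
#'
#' @param name motif name.
#' @param consensus string over A,C,G,T,R,Y,S,W,K,M,N.
#' @return object of class `motif`.
#' @export
#' @examples
#' hre_motif()  # the RCGTG core
motif <- function(name, consensus) {
  consensus <- toupper(consensus)
  letters_ <- strsplit(consensus, "", fixed = TRUE)[[1]]
  if (!length(letters_)) stop("empty motif consensus", call. = FALSE)
  bad <- setdiff(letters_, names(.iupac_sets))
  if (length(bad))
    stop("invalid motif letter(s): ", paste(bad, collapse = ","), call. = FALSE)
  structure(list(name = name, consensus = consensus), class = "motif")
}

#' @rdname motif
#' @export
hre_motif <- function() motif("HRE", "RCGTG")

#' Reverse complement of a DNA/IUPAC string
#' @param seq character string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  ch <- rev(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  out <- .iupac_comp[ch]
  if (anyNA(out)) stop("cannot complement letter(s): ",
                       paste(unique(ch[is.na(out)]), collapse = ","),
                       call. = FALSE)
  paste(out, collapse = "")
}

# positions (0-based) where `mot_letters` matches the + strand of `chars`
.match_positions <- function(chars, mot_letters) {
  L <- length(chars)
  m <- length(mot_letters)
  if (L < m) return(integer())
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    allowed <- .iupac_sets[[mot_letters[j]]]
    ok <- ok & (chars[j:(L - m + j)] %in% allowed)
  }
  which(ok) - 1L
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Finds every position where the consensus matches the forward strand and,
#' if `both_strands`, every position where the reverse complement of the
#' sequence window matches (reported in + strand coordinates). An `N` in the
#' subject sequence never matches any motif letter. Overlapping hits are all
#' reported; output is sorted by start, `+` before `-` at equal start.
#'
#' @param seq DNA string over A,C,G,T,N.
#' @param mot a [motif()].
#' @param both_strands scan the reverse strand too (default TRUE; the HRE is
#'   not palindromic but its function is orientation-independent).
#' @param seq_name name recorded in the hit table.
#' @return data.frame (seq_name, start, end, strand, matched) with 0-based
#'   half-open hit coordinates; `matched` is the text as read on the + strand.
#' @export
scan_motif <- function(seq, mot, both_strands = TRUE, seq_name = "seq") {
  stopifnot(inherits(mot, "motif"))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))))
    stop("sequence contains invalid letter(s): ", paste(bad, collapse = ","),
         call. = FALSE)
  fwd <- strsplit(mot$consensus, "", fixed = TRUE)[[1]]
  m <- length(fwd)
  pos <- .match_positions(chars, fwd)
  strand <- rep("+", length(pos))
  if (both_strands) {
    # a - strand hit at [i, i+m) means revcomp(window) matches the consensus,
    # equivalently the window matches revcomp(consensus) on the + strand
    rcpos <- .match_positions(chars, strsplit(revcomp(mot$consensus), "",
                                              fixed = TRUE)[[1]])
    pos <- c(pos, rcpos)
    strand <- c(strand, rep("-", length(rcpos)))
  }
  ord <- order(pos, strand)
  pos <- pos[ord]
  strand <- strand[ord]
  matched <- if (length(pos)) substring(seq, pos + 1L, pos + m) else character(0)
  data.frame(seq_name = rep(seq_name, length(pos)), start = pos,
             end = pos + m, strand = strand, matched = matched,
             stringsAsFactors = FALSE)
}

#' Scan a set of named sequences
#' @param seqs named character vector.
#' @inheritParams scan_motif
#' @return row-bound hit data.frame across all sequences.
#' @export
scan_motif_set <- function(seqs, mot, both_strands = TRUE) {
  hits <- lapply(seq_along(seqs), function(i)
    scan_motif(seqs[[i]], mot, both_strands, seq_name = names(seqs)[i]))
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

#' Count sequences containing at least one motif hit
#'
#' Presence/absence (ZOOPS-like) counting, the statistic fed to the binomial
#' enrichment test.
#'
#' @inheritParams scan_motif_set
#' @return list(k = number of sequences with >= 1 hit, n = total sequences).
#' @export
count_sequences_with_hit <- function(seqs, mot, both_strands = TRUE) {
  stopifnot(inherits(mot, "motif"))
  fwd <- strsplit(mot$consensus, "", fixed = TRUE)[[1]]
  rev_ <- strsplit(revcomp(mot$consensus), "", fixed = TRUE)[[1]]
  has <- vapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    length(.match_positions(chars, fwd)) > 0 ||
      (both_strands && length(.match_positions(chars, rev_)) > 0)
  }, TRUE)
  list(k = sum(unname(has)), n = length(seqs))
}

#' Background matching specification
#'
#' @param gc_bins number of equal-width GC-fraction bins on \[0,1\].
#' @param length_bins number of equal-width length bins over the pool's
#'   length range (1 = ignore length; promoters here are fixed-length).
#' @param n_background_per_target background sequences drawn per target.
#' @param seed RNG seed for sampling.
#' @export
background_spec <- function(gc_bins = 10L, length_bins = 1L,
                            n_background_per_target = 1L, seed = 1L) {
  stopifnot(gc_bins >= 1, length_bins >= 1, n_background_per_target >= 1)
  structure(list(gc_bins = as.integer(gc_bins),
                 length_bins = as.integer(length_bins),
                 n_background_per_target = as.integer(n_background_per_target),
                 seed = as.integer(seed)),
            class = "background_spec")
}

.gc_fraction <- function(seqs) {
  gc <- nchar(gsub("[^GC]", "", seqs))
  acgt <- nchar(gsub("[^ACGT]", "", seqs))
  ifelse(acgt == 0, 0, gc / acgt)
}

.bin_index <- function(x, n_bins, lo, hi) {
  if (n_bins == 1L || hi <= lo) return(rep(1L, length(x)))
  pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
}

#' Sample a GC- and length-matched background sequence set
#'
#' For each target sequence, draws `n_background_per_target` pool sequences
#' from the pool bin matching the target's (GC bin, length bin). Within a bin
#' sampling is without replacement until the bin is exhausted, then with
#' replacement (with a warning). Deterministic under the given seed.
#'
#' @param targets,pool character vectors of sequences (pool non-empty).
#' @param spec a [background_spec()].
#' @return character vector of sampled background sequences (named by their
#'   pool names when present).
#' @export
sample_matched_background <- function(targets, pool, spec = background_spec()) {
  if (!length(pool)) stop("background pool is empty", call. = FALSE)
  gc_t <- .gc_fraction(targets)
  gc_p <- .gc_fraction(pool)
  len_p <- nchar(pool)
  len_t <- nchar(targets)
  lo <- min(len_p); hi <- max(len_p) + 1e-9
  bin_t <- paste(.bin_index(gc_t, spec$gc_bins, 0, 1),
                 .bin_index(pmin(pmax(len_t, lo), hi), spec$length_bins, lo, hi))
  bin_p <- paste(.bin_index(gc_p, spec$gc_bins, 0, 1),
                 .bin_index(len_p, spec$length_bins, lo, hi))
  out <- character(0)
  warned <- FALSE
  withr::with_seed(spec$seed, {
    for (b in unique(bin_t)) {
      need <- sum(bin_t == b) * spec$n_background_per_target
      avail <- which(bin_p == b)
      if (!length(avail))
        stop("no pool sequences in bin (gc_bin length_bin) = ", b, call. = FALSE)
      if (length(avail) >= need) {
        idx <- sample(avail, need)
      } else {
        idx <- c(sample(avail, length(avail)),
                 sample(avail, need - length(avail), replace = TRUE))
        warned <- TRUE
      }
      out <- c(out, pool[idx])
    }
  })
  if (warned) warning("background bin exhausted; sampled with replacement")
  out
}
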