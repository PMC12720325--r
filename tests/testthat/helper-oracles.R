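# Independent oracles. These deliberately re-derive results by brute force
# (window enumeration, naive agglomeration, direct pmf summation) and stay
# independent of the code paths they check.

oracle_sets <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# enumerate every window; a window matches if each character is in the IUPAC
# set of the corresponding motif letter; reverse-strand matches are windows
# whose reverse complement matches the consensus. The per-window loop with a
# letter-by-position lookup table is deliberately different from any rolling
# vectorisation an implementation would use.
oracle_scan <- function(seq, consensus, both_strands = TRUE) {
  subject_letters <- c("A", "C", "G", "T", "N")
  m <- nchar(consensus)
  L <- nchar(seq)
  mc <- strsplit(consensus, "")[[1]]
  # allowed[letter, position]: does subject letter satisfy motif position?
  allowed <- vapply(mc, function(b) subject_letters %in% oracle_sets[[b]],
                    logical(5))
  ci <- match(strsplit(seq, "")[[1]], subject_letters)
  starts <- integer(); strands <- character()
  if (L >= m) {
    for (i in 0:(L - m)) {
      wi <- ci[(i + 1):(i + m)]
      if (all(allowed[cbind(wi, 1:m)])) {
        starts <- c(starts, i); strands <- c(strands, "+")
      }
      if (both_strands) {
        # reverse complement of the window, as subject letter indices
        # (A<->T is 1<->4, C<->G is 2<->3, N stays 5)
        rwi <- rev(c(4L, 3L, 2L, 1L, 5L)[wi])
        if (all(allowed[cbind(rwi, 1:m)])) {
          starts <- c(starts, i); strands <- c(strands, "-")
        }
      }
    }
  }
  if (!length(starts))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), matched = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(start = starts, end = starts + m, strand = strands,
                    matched = substring(seq, starts + 1, starts + m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_iupac_motif <- function(len) {
  # bias toward concrete letters so random motifs still hit occasionally
  pool <- c(rep(c("A", "C", "G", "T"), 3), "R", "Y", "S", "W", "K", "M", "N")
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

# naive O(n^3) Lance-Williams Ward agglomeration; returns merge heights and
# the partition (membership vector) after each merge, ties broken by the
# smallest (i, j) cluster-index pair
oracle_ward <- function(m, variant = c("ward_d", "ward_d2")) {
  variant <- match.arg(variant)
  n <- nrow(m)
  D <- as.matrix(stats::dist(m))
  if (variant == "ward_d2") D <- D^2
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    idx <- which(active)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      if (D[i, j] < best_d - 1e-12) { best_d <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- D[i, j]
    ni <- sizes[i]; nj <- sizes[j]
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active[j] <- FALSE
    lab <- integer(n)
    for (ci in which(active)) lab[members[[ci]]] <- ci
    partitions[[step]] <- lab
  }
  if (variant == "ward_d2") heights <- sqrt(heights)
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition: relabel clusters by first appearance
canon_partition <- function(lab) as.integer(factor(lab, levels = unique(lab)))

# direct pmf summation oracle for the upper binomial tail
oracle_binom_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p0))
}

# generate n sequences of given length/GC, planting one RCGTG instance
# (random R, random strand, random position) in a `frac` fraction
planted_seqs <- function(n, len, gc, frac, prefix = "s") {
  seqs <- vapply(seq_len(n), function(i) random_dna(len, gc), "")
  planted <- seq_len(round(frac * n))
  for (i in planted) {
    core <- paste0(sample(c("A", "G"), 1), "CGTG")
    if (sample(c(TRUE, FALSE), 1)) core <- oracle_revcomp(core)
    pos <- sample(len - 4, 1)
    substr(seqs[i], pos, pos + 4) <- core
  }
  names(seqs) <- sprintf("%s%03d", prefix, seq_len(n))
  seqs
}
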