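# Known-motif enrichment by cumulative binomial against a matched background,
# plus Benjamini-Hochberg adjustment.

#' Cumulative binomial enrichment p-value
#'
#' The background hit fraction p0 = k_background / n_background is the null
#' success probability; the p-value is P(X >= k_target) for
#' X ~ Binomial(n_target, p0), evaluated via the numerically stable upper
#' tail. When the background count is degenerate (0 or n), p0 is clamped to
#' [eps, 1 - eps] with eps = 1 / (2 n_background) to avoid p = 0/1 artifacts
#' from a finite background. One-sided (over-representation only).
#'
#' @param k_target,n_target hit-bearing and total target sequences.
#' @param k_background,n_background same for the background set.
#' @return the enrichment p-value.
#' @export
binomial_enrichment <- function(k_target, n_target, k_background,
                                n_background) {
  stopifnot(n_background > 0, n_target >= 0)
  if (k_target > n_target || k_background > n_background)
    stop("k cannot exceed n", call. = FALSE)
  if (k_target < 0 || k_background < 0) stop("negative counts", call. = FALSE)
  p0 <- k_background / n_background
  eps <- 1 / (2 * n_background)
  if (k_background == 0) p0 <- eps
  if (k_background == n_background) p0 <- 1 - eps
  if (k_target == 0) return(1)
  # P(X >= k) = upper tail at k-1
  stats::pbinom(k_target - 1, n_target, p0, lower.tail = FALSE)
}

#' Known-motif enrichment over a motif panel
#'
#' Counts sequences with at least one hit (presence/absence) in the target
#' and background sets for each motif, computes the cumulative-binomial
#' p-value, sorts by p ascending, and fills the Benjamini-Hochberg column
#' across the panel.
#'
#' @param target_seqs,background_seqs character vectors of sequences.
#' @param motifs list of [motif()] objects.
#' @param both_strands scan both strands (default TRUE).
#' @return data.frame (motif_name, consensus, n_target, k_target,
#'   n_background, k_background, background_fraction, p_value, bh_adjusted),
#'   sorted by p_value.
#' @export
run_known_motif_enrichment <- function(target_seqs, background_seqs, motifs,
                                       both_strands = TRUE) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  rows <- lapply(motifs, function(mot) {
    t <- count_sequences_with_hit(target_seqs, mot, both_strands)
    b <- count_sequences_with_hit(background_seqs, mot, both_strands)
    data.frame(motif_name = mot$name, consensus = mot$consensus,
               n_target = t$n, k_target = t$k,
               n_background = b$n, k_background = b$k,
               background_fraction = if (b$n > 0) b$k / b$n else NA_real_,
               p_value = binomial_enrichment(t$k, t$n, b$k, b$n),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res$bh_adjusted <- benjamini_hochberg(res$p_value)
  res <- res[order(res$p_value, res$motif_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' adj_i = min over j with rank >= rank(i) of m * p_(j) / j, capped at 1;
#' input order is preserved.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[ord]))
  adj[order(ord)]
}
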