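# Hierarchical clustering (euclidean + Ward), two-level dendrogram cutting,
# the between-minus-within cluster-separation statistic, and its Monte-Carlo
# and exhaustive permutation tests.

#' Clustering configuration
#'
#' `ward_d` is R's "ward.D": Lance-Williams Ward updates applied to
#' UNsquared Euclidean distances; `ward_d2` is classical Ward on squared
#' distances. Rows are not standardised before clustering.
#'
#' @param distance only "euclidean".
#' @param linkage "ward_d" or "ward_d2".
#' @param first_cut_height dendrogram height for the primary cut
#'   (default 50, on the data's own scale).
#' @param subdivide_k number of subclusters at the second-level cut
#'   (default 2).
#' @export
cluster_config <- function(distance = "euclidean",
                           linkage = c("ward_d", "ward_d2"),
                           first_cut_height = 50, subdivide_k = 2L) {
  linkage <- match.arg(linkage)
  stopifnot(distance == "euclidean", first_cut_height > 0, subdivide_k >= 2)
  structure(list(distance = distance, linkage = linkage,
                 first_cut_height = first_cut_height,
                 subdivide_k = as.integer(subdivide_k)),
            class = "cluster_config")
}

#' Agglomerative hierarchical clustering of matrix rows
#'
#' @param m numeric matrix (>= 2 rows, no missing values).
#' @param config a [cluster_config()].
#' @return an [stats::hclust] object.
#' @export
hierarchical_cluster <- function(m, config = cluster_config()) {
  if (anyNA(m))
    stop("matrix contains missing values; run drop_na_rows first",
         call. = FALSE)
  if (nrow(m) < 2) stop("need >= 2 rows to cluster", call. = FALSE)
  d <- stats::dist(m, method = "euclidean")
  method <- if (config$linkage == "ward_d") "ward.D" else "ward.D2"
  stats::hclust(d, method = method)
}

#' Cut a dendrogram by height or into k clusters
#'
#' Exactly one of `height`/`k` must be given. Height mode removes all merges
#' above the height and labels the resulting connected components; k mode
#' cuts to exactly k clusters. Labels are relabelled contiguously from 1 in
#' order of first appearance.
#'
#' @param hc an [stats::hclust] object.
#' @param height,k cut parameters (give exactly one).
#' @return list (item_ids, labels, level) of class `cluster_assignment`;
#'   `level` is "primary" for a height cut, "subdivided" for a k cut.
#' @export
cut_dendrogram <- function(hc, height = NULL, k = NULL) {
  if (is.null(height) == is.null(k))
    stop("give exactly one of height / k", call. = FALSE)
  raw <- if (!is.null(height)) stats::cutree(hc, h = height)
         else stats::cutree(hc, k = k)
  labels <- as.integer(factor(raw, levels = unique(raw)))
  structure(list(item_ids = if (!is.null(hc$labels)) hc$labels
                            else as.character(seq_along(raw)),
                 labels = labels,
                 level = if (!is.null(height)) "primary" else "subdivided"),
            class = "cluster_assignment")
}

.as_dist_matrix <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8) || any(diag(m) != 0))
    stop("need a symmetric distance matrix with zero diagonal", call. = FALSE)
  m
}

#' Cluster-separation statistic
#'
#' The difference between the mean between-cluster distance and the mean
#' within-cluster distance over all unordered item pairs. Invariant to
#' cluster relabelling and item reordering.
#'
#' @param d distance matrix (or `dist`).
#' @param labels cluster label per item (>= 2 clusters; at least one
#'   within-cluster pair overall).
#' @return the statistic (between mean minus within mean).
#' @export
separation_statistic <- function(d, labels) {
  m <- .as_dist_matrix(d)
  n <- nrow(m)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2)
    stop("need >= 2 clusters", call. = FALSE)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  same <- labels[pairs[, 1]] == labels[pairs[, 2]]
  if (!any(same))
    stop("all clusters are singletons: no within-cluster pairs", call. = FALSE)
  vals <- m[pairs]
  mean(vals[!same]) - mean(vals[same])
}

# fast path used by the permutation loop: precomputed pair indices
.sep_stat_fast <- function(vals, i1, i2, labels) {
  same <- labels[i1] == labels[i2]
  mean(vals[!same]) - mean(vals[same])
}

#' Monte-Carlo permutation test for cluster separation
#'
#' For each permutation the cluster labels are randomly reassigned while
#' preserving the original group sizes and the separation statistic is
#' recomputed. The default p-value is the literal proportion of permutations
#' whose statistic is >= the observed value (which can be 0); `add_one` gives
#' the standard (count + 1) / (n + 1) variant.
#'
#' @param d distance matrix (or `dist`).
#' @param labels observed cluster labels.
#' @param n_permutations number of label reassignments (default 999).
#' @param seed RNG seed (deterministic given the seed).
#' @param add_one use the (count+1)/(n+1) rule.
#' @return list of class `cluster_permutation_result`: observed_stat,
#'   n_permutations, n_at_least_as_extreme, p_value, mode, seed.
#' @export
permutation_test <- function(d, labels, n_permutations = 999L, seed = 1L,
                             add_one = FALSE) {
  m <- .as_dist_matrix(d)
  obs <- separation_statistic(m, labels)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  i1 <- pairs[, 1]; i2 <- pairs[, 2]
  vals <- m[pairs]
  count <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample(labels)
      if (.sep_stat_fast(vals, i1, i2, perm) >= obs) count <- count + 1L
    }
  })
  p <- if (add_one) (count + 1) / (n_permutations + 1) else count / n_permutations
  structure(list(observed_stat = obs, n_permutations = as.integer(n_permutations),
                 n_at_least_as_extreme = count, p_value = p,
                 mode = "monte_carlo", seed = as.integer(seed),
                 add_one = isTRUE(add_one)),
            class = "cluster_permutation_result")
}

# all assignments of `sizes` labels to n items, as a list of label vectors;
# built by recursive choice of positions for each label class
.enumerate_assignments <- function(n, sizes) {
  labs <- names(sizes)
  rec <- function(avail, si) {
    if (si == length(sizes))
      return(list(stats::setNames(rep(labs[si], length(avail)), avail)))
    combs <- utils::combn(avail, sizes[si], simplify = FALSE)
    out <- list()
    for (cb in combs) {
      sub <- rec(setdiff(avail, cb), si + 1L)
      for (s in sub)
        out[[length(out) + 1L]] <- c(stats::setNames(rep(labs[si], length(cb)), cb), s)
    }
    out
  }
  lapply(rec(seq_len(n), 1L), function(x) {
    lab <- character(n)
    lab[as.integer(names(x))] <- x
    lab
  })
}

#' Exhaustive permutation test for cluster separation
#'
#' Enumerates every size-preserving label arrangement (the observed one
#' included) and reports the exact proportion with statistic >= observed.
#' Serves as the exact-null oracle for [permutation_test()].
#'
#' @inheritParams permutation_test
#' @param max_arrangements refuse to enumerate beyond this many (default 1e6).
#' @return `cluster_permutation_result` with mode "exhaustive".
#' @export
exhaustive_permutation_test <- function(d, labels, max_arrangements = 1e6) {
  m <- .as_dist_matrix(d)
  obs <- separation_statistic(m, labels)
  sizes <- table(labels)
  total <- exp(lgamma(length(labels) + 1) - sum(lgamma(sizes + 1)))
  if (total > max_arrangements)
    stop("too many arrangements to enumerate: ", format(total), call. = FALSE)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  i1 <- pairs[, 1]; i2 <- pairs[, 2]
  vals <- m[pairs]
  arrangements <- .enumerate_assignments(length(labels),
                                         stats::setNames(as.integer(sizes),
                                                         names(sizes)))
  stats_all <- vapply(arrangements, function(lab)
    .sep_stat_fast(vals, i1, i2, lab), 0)
  count <- sum(stats_all >= obs - 1e-12)
  structure(list(observed_stat = obs,
                 n_permutations = length(arrangements),
                 n_at_least_as_extreme = as.integer(count),
                 p_value = count / length(arrangements),
                 mode = "exhaustive", seed = NA_integer_, add_one = FALSE),
            class = "cluster_permutation_result")
}

#' @export
print.cluster_permutation_result <- function(x, ...) {
  cat(sprintf("%s permutation test: stat = %.4g, p = %.4g (%d/%d >= observed)\n",
              x$mode, x$observed_stat, x$p_value, x$n_at_least_as_extreme,
              x$n_permutations))
  invisible(x)
}

#' Per-cluster mean expression trajectories
#'
#' Mean matrix value per cluster x genotype x condition x timepoint, the
#' numeric content of the usual cluster line plots (WT vs KO trajectories).
#'
#' @param em an `expr_matrix`.
#' @param assignment a `cluster_assignment` over (a subset of) the matrix
#'   rows.
#' @return data.frame (cluster, genotype, condition, timepoint_h, mean_value,
#'   n_genes).
#' @export
cluster_mean_profiles <- function(em, assignment) {
  s <- em$samples
  grp <- interaction(s$genotype, s$condition, s$timepoint_h, drop = TRUE)
  out <- list()
  for (cl in sort(unique(assignment$labels))) {
    ids <- assignment$item_ids[assignment$labels == cl]
    sub <- em$values[ids, , drop = FALSE]
    for (g in levels(grp)) {
      cols <- grp == g
      meta <- s[which(cols)[1], ]
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, genotype = meta$genotype, condition = meta$condition,
        timepoint_h = meta$timepoint_h,
        mean_value = mean(sub[, cols, drop = FALSE]),
        n_genes = length(ids), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
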