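# Resampling-based consensus clustering over samples with PAC/delta-area
# k-selection, plus a PCA embedding for pattern-separation checks. Base
# clusterer: k-medoids (PAM) on 1 - Pearson correlation distance.

# 1 - Pearson correlation distance between sample columns, computed on
# gene-standardized values so between-gene baseline differences do not
# swamp the sample-to-sample structure (constant genes carry no signal
# and are dropped silently here)
correlation_distance <- function(x) {
  if (nrow(x) < 2L) abort_icp("need >= 2 genes for correlation distance")
  sdv <- apply(x, 1L, stats::sd)
  z <- (x[sdv > 0, , drop = FALSE] - rowMeans(x[sdv > 0, , drop = FALSE])) /
    sdv[sdv > 0]
  1 - stats::cor(z)
}

#' Consensus clustering of samples
#'
#' Repeatedly subsamples items (samples), partitions each subsample with
#' PAM on 1 - Pearson correlation distance, and records for every sample
#' pair the fraction of co-sampled runs in which the pair co-clustered.
#' Final assignments cut an average-linkage dendrogram of `1 - M` at `k`.
#'
#' @param expr genes x samples matrix (e.g. the 31-gene panel rows).
#' @param k number of clusters, `2 <= k < n_samples`.
#' @param n_resamples number of subsampling runs (>= 2; default 1000).
#' @param item_fraction fraction of samples drawn per run, in (0, 1\].
#' @param seed optional integer seed.
#' @param dist sample dissimilarity: `"euclidean"` (default; Euclidean on
#'   gene-standardized values, which retains panel-wide shifts) or
#'   `"pearson"` (1 - Pearson profile correlation; blind to a shared
#'   shift across the panel, and noisy on gene sets as small as the
#'   checkpoint panel - see the methods vignette).
#' @return list of class `consensus_result`: `k`, `consensus` (samples x
#'   samples matrix in \[0,1\], diagonal 1), `assignments` (named integer
#'   1..k), `n_resamples`, `item_fraction`.
#' @export
consensus_cluster <- function(expr, k, n_resamples = 1000L,
                              item_fraction = 0.8, seed = NULL,
                              dist = c("euclidean", "pearson")) {
  dist <- match.arg(dist)
  n <- ncol(expr)
  if (k < 2L) abort_icp("k must be >= 2")
  if (k >= n) abort_icp("k must be smaller than the number of samples")
  if (n_resamples < 2L) abort_icp("need >= 2 resamples")
  if (item_fraction <= 0 || item_fraction > 1)
    abort_icp("item_fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)

  D <- if (dist == "pearson") {
    correlation_distance(expr)
  } else {
    sdv <- apply(expr, 1L, stats::sd)
    z <- (expr[sdv > 0, , drop = FALSE] -
            rowMeans(expr[sdv > 0, , drop = FALSE])) / sdv[sdv > 0]
    as.matrix(stats::dist(t(z)))
  }
  m <- max(2L, as.integer(floor(item_fraction * n)))
  co_cluster <- matrix(0, n, n)
  co_sample <- matrix(0, n, n)
  for (r in seq_len(n_resamples)) {
    idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
    fit <- cluster::pam(stats::as.dist(D[idx, idx]), k,
                        diss = TRUE, cluster.only = TRUE)
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    for (cl in seq_len(k)) {
      members <- idx[fit == cl]
      co_cluster[members, members] <- co_cluster[members, members] + 1
    }
  }
  M <- matrix(0, n, n)
  seen <- co_sample > 0
  M[seen] <- co_cluster[seen] / co_sample[seen]
  off <- seen; diag(off) <- TRUE
  if (!all(off))
    warning("some sample pairs were never co-sampled; their consensus is 0")
  diag(M) <- 1
  dimnames(M) <- list(colnames(expr), colnames(expr))

  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  assignments <- stats::cutree(hc, k = k)
  structure(list(k = k, consensus = M, assignments = assignments,
                 n_resamples = n_resamples, item_fraction = item_fraction),
            class = "consensus_result")
}

# empirical CDF area and PAC for one consensus matrix
consensus_cdf_stats <- function(M, u1, u2) {
  vals <- M[upper.tri(M)]
  pac <- mean(vals > u1 & vals <= u2)
  # area under the right-continuous ECDF on [0, 1]
  F <- stats::ecdf(vals)
  xs <- c(0, sort(unique(vals)), 1)
  area <- sum(diff(xs) * F(xs[-length(xs)]))
  list(pac = pac, area = area, cdf = F)
}

#' Select the number of clusters from a consensus grid
#'
#' Computes, for every `k` on the grid, the empirical CDF of off-diagonal
#' consensus entries, the proportion of ambiguous clustering
#' `PAC = F(u2) - F(u1)`, and the relative change in area under the CDF
#' (delta-area, defined from the second grid point on). The chosen `k`
#' minimizes PAC, ties broken toward smaller `k`.
#'
#' @param results list of `consensus_result` objects over >= 3 consecutive
#'   `k` values.
#' @param u1,u2 ambiguity interval (default 0.1, 0.9).
#' @return list of class `k_selection`: `k_grid`, `pac`, `area`,
#'   `delta_area` (NA for the first grid point), `cdf` (list of ECDFs),
#'   `chosen_k`.
#' @export
select_k <- function(results, u1 = 0.1, u2 = 0.9) {
  if (length(results) == 0L) abort_icp("empty consensus grid")
  ks <- vapply(results, function(r) as.integer(r$k), 0L)
  ord <- order(ks)
  results <- results[ord]; ks <- ks[ord]
  if (length(ks) < 3L || !all(diff(ks) == 1L))
    abort_icp("k grid must cover >= 3 consecutive values")
  stats_k <- lapply(results, function(r)
    consensus_cdf_stats(r$consensus, u1, u2))
  pac <- vapply(stats_k, `[[`, 0, "pac")
  area <- vapply(stats_k, `[[`, 0, "area")
  delta_area <- c(NA_real_, diff(area) / area[-length(area)])
  chosen <- ks[which.min(pac)]   # which.min takes the first = smallest k
  structure(list(k_grid = ks, pac = stats::setNames(pac, ks),
                 area = stats::setNames(area, ks),
                 delta_area = stats::setNames(delta_area, ks),
                 cdf = lapply(stats_k, `[[`, "cdf"),
                 chosen_k = chosen, u1 = u1, u2 = u2),
            class = "k_selection")
}

#' PCA embedding of samples
#'
#' Projects samples onto the top principal components of the gene-
#' standardized matrix (genes z-scored; constant genes dropped with a
#' warning).
#'
#' @param expr genes x samples matrix.
#' @param d number of components, `d <= min(genes, samples)`.
#' @return list of class `pca_embedding`: `coordinates` (samples x d),
#'   `explained` (variance fractions, non-increasing), `rotation`.
#' @export
pca_embed <- function(expr, d = 2L) {
  std <- standardize_rows(expr)
  z <- std$z
  if (d > min(nrow(z), ncol(z)))
    abort_icp("d exceeds min(genes, samples) after dropping constant genes")
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = pc$x[, seq_len(d), drop = FALSE],
                 explained = explained[seq_len(d)],
                 rotation = pc$rotation[, seq_len(d), drop = FALSE],
                 dropped = std$dropped),
            class = "pca_embedding")
}

#' Canonicalize pattern labels by mean panel expression
#'
#' Renames clusters "A", "B", "C", ... in decreasing order of their mean
#' expression over the supplied panel rows, so "A" is always the
#' high-expression (immune-hot) pattern and labels are comparable across
#' runs.
#'
#' @param assignments named cluster labels (from [consensus_cluster()]).
#' @param expr genes x samples matrix restricted to the panel used for
#'   clustering; columns must cover the assignment names.
#' @return named character vector of labels "A", "B", ...
#' @export
canonicalize_patterns <- function(assignments, expr) {
  ids <- names(assignments)
  if (is.null(ids) || !all(ids %in% colnames(expr)))
    abort_icp("assignments must be named by sample ids present in expr")
  cl <- sort(unique(assignments))
  mean_expr <- vapply(cl, function(c)
    mean(expr[, ids[assignments == c], drop = FALSE]), 0)
  new <- LETTERS[rank(-mean_expr, ties.method = "first")]
  stats::setNames(new[match(assignments, cl)], ids)
}
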