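# Single-sample rank-walk enrichment (ssGSEA), ESTIMATE-style stromal and
# immune scores, and score-score association statistics (Spearman and
# distance correlation).

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each sample, genes are ranked by expression (average ranks on ties)
#' and walked in decreasing order; the enrichment score of a set is the sum
#' over positions of the difference between the weighted in-set cumulative
#' fraction (weights `rank^alpha`, normalized to 1) and the uniform
#' out-of-set cumulative fraction. Scores depend only on within-sample
#' ranks, so they are invariant to any strictly monotone transform of a
#' sample's expression values. If a set covers every gene in the matrix the
#' out-of-set step is empty and the score is the in-set walk alone.
#'
#' @param expr genes x samples matrix.
#' @param sets named list of gene vectors; sets sharing no gene with the
#'   matrix are dropped with a warning.
#' @param alpha rank weight exponent (>= 0; default 0.25, the conventional
#'   ssGSEA weight).
#' @param normalize `"none"` (default) or `"minmax"` (each set's row
#'   rescaled to \[0,1\] across samples).
#' @return sets x samples score matrix; dropped set names in
#'   `attr(, "dropped")`.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25,
                   normalize = c("none", "minmax")) {
  normalize <- match.arg(normalize)
  if (alpha < 0) abort_icp("alpha must be >= 0")
  genes <- rownames(expr)
  n <- length(genes)
  overlap <- lapply(sets, function(s) which(genes %in% s))
  empty <- lengths(overlap) == 0L
  if (any(empty)) {
    warning("dropping set(s) with no gene in the matrix: ",
            paste(names(sets)[empty], collapse = ", "))
    overlap <- overlap[!empty]
  }
  if (length(overlap) == 0L) abort_icp("no set overlaps the matrix")

  member <- matrix(FALSE, n, length(overlap))
  for (j in seq_along(overlap)) member[overlap[[j]], j] <- TRUE

  scores <- matrix(NA_real_, length(overlap), ncol(expr),
                   dimnames = list(names(overlap), colnames(expr)))
  for (s in seq_len(ncol(expr))) {
    x <- expr[, s]
    r <- rank(x, ties.method = "average")
    ord <- order(-x, seq_len(n))         # descending walk, stable on ties
    w_all <- r[ord]^alpha
    memb <- member[ord, , drop = FALSE]
    for (j in seq_len(ncol(memb))) {
      inset <- memb[, j]
      w <- w_all * inset
      p_in <- cumsum(w) / sum(w)
      n_out <- n - sum(inset)
      p_out <- if (n_out == 0L) 0 else cumsum(!inset) / n_out
      scores[j, s] <- sum(p_in - p_out)
    }
  }
  if (normalize == "minmax") {
    rng <- apply(scores, 1L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    scores <- (scores - rng[1L, ]) / span
  }
  attr(scores, "dropped") <- names(sets)[empty]
  attr(scores, "alpha") <- alpha
  scores
}

#' ESTIMATE-style stromal, immune and combined scores
#'
#' Stromal and immune scores are the unnormalized [ssgsea()] scores of the
#' two supplied signatures; the combined score is their sum.
#'
#' @param expr genes x samples matrix.
#' @param stromal_set,immune_set gene vectors; each must share at least
#'   one gene with the matrix.
#' @param alpha rank weight exponent passed to [ssgsea()].
#' @return data.frame with `sample_id`, `StromalScore`, `ImmuneScore`,
#'   `ESTIMATEScore` (= stromal + immune, exactly).
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, alpha = 0.25) {
  if (!any(stromal_set %in% rownames(expr)))
    abort_icp("stromal signature shares no gene with the matrix")
  if (!any(immune_set %in% rownames(expr)))
    abort_icp("immune signature shares no gene with the matrix")
  sc <- ssgsea(expr, list(stromal = stromal_set, immune = immune_set),
               alpha = alpha, normalize = "none")
  data.frame(sample_id = colnames(expr),
             StromalScore = sc["stromal", ],
             ImmuneScore = sc["immune", ],
             ESTIMATEScore = sc["stromal", ] + sc["immune", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

# sample distance correlation via double-centered Euclidean distance
# matrices
dcor_stat <- function(x, y) {
  a <- as.matrix(stats::dist(x))
  b <- as.matrix(stats::dist(y))
  A <- a - rowMeans(a) - rep(colMeans(a), each = nrow(a)) + mean(a)
  B <- b - rowMeans(b) - rep(colMeans(b), each = nrow(b)) + mean(b)
  dcov2 <- mean(A * B)
  dvar_x <- mean(A * A); dvar_y <- mean(B * B)
  if (dvar_x <= 0 || dvar_y <= 0) return(NA_real_)
  sqrt(max(dcov2, 0)) / (dvar_x * dvar_y)^(1 / 4)
}

#' Correlation between two per-sample score vectors
#'
#' `method = "spearman"`: Pearson correlation on average-ranked data with a
#' t-approximation p-value. `method = "distance"`: sample distance
#' correlation (double-centered Euclidean distance matrices) with a
#' seeded permutation p-value.
#'
#' @param x,y numeric vectors of equal length >= 4, finite.
#' @param method `"spearman"` or `"distance"`.
#' @param n_perm permutations for the distance-correlation null
#'   (default 999).
#' @param seed optional seed for the permutation null.
#' @return list with `statistic` and `p_value` (both `NA` with a warning
#'   when either input is constant).
#' @export
correlate <- function(x, y, method = c("spearman", "distance"),
                      n_perm = 999L, seed = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort_icp("x and y differ in length")
  if (length(x) < 4L) abort_icp("need >= 4 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    abort_icp("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  if (method == "spearman") {
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    rho <- stats::cor(rx, ry)
    n <- length(x)
    if (abs(rho) >= 1) return(list(statistic = rho, p_value = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    list(statistic = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
  } else {
    if (!is.null(seed)) set.seed(seed)
    obs <- dcor_stat(x, y)
    perm <- vapply(seq_len(n_perm), function(i)
      dcor_stat(x, sample(y)), 0)
    list(statistic = obs,
         p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
  }
}
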