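#' @keywords internal
"_PACKAGE"

# fail with a consistent message prefix
abort_icp <- function(...) stop(..., call. = FALSE)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items.
#' Used to score recovery of planted pattern labels.
#'
#' @param a,b vectors of cluster labels (any type coercible to factor),
#'   equal length.
#' @return A single number in \[-1, 1\]; 1 means identical partitions up to
#'   relabeling, 0 is the chance level.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort_icp("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# derive a per-stage RNG seed from one global seed via a fixed name table,
# so adding stages never perturbs earlier stages' substreams
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, batch = 2L, cluster_icg = 3L, enrich = 4L,
               degs = 5L, cluster_genes = 6L, icscore = 7L, cutpoint = 8L,
               survival = 9L, genomics = 10L, misc = 11L)
  if (!stage %in% names(offsets)) abort_icp("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]] * 9973) %% 2147483647)
}

# z-score matrix rows; constant rows dropped with a warning
standardize_rows <- function(x, warn = TRUE) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, stats::sd)
  keep <- sdv > 0
  if (!all(keep) && warn) {
    warning(sum(!keep), " constant gene(s) dropped before standardization")
  }
  list(z = (x[keep, , drop = FALSE] - mu[keep]) / sdv[keep],
       mean = mu[keep], sd = sdv[keep], dropped = rownames(x)[!keep])
}
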