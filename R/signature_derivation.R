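# Derivation of the immune-checkpoint signature: pattern-contrast DEGs and
# their intersection, the PCA-based ICscore with a fixed sign convention,
# and the survival-optimal (maximally selected log-rank) cutpoint.

# vectorized two-sample Welch t per gene (rows)
welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero-variance genes with equal means: no evidence either way
  p[is.na(p) & abs(m1 - m2) < .Machine$double.eps] <- 1
  data.frame(statistic = tstat, p = p)
}

#' Differential expression between patterns and the intersection gene set
#'
#' Runs a two-sample test per gene for every unordered pair of pattern
#' labels (Welch t on log expression by default, Wilcoxon rank-sum as an
#' option), adjusts p-values by Benjamini-Hochberg within each contrast,
#' and returns the intersection of the per-contrast significant sets -
#' the pattern-associated signature genes.
#'
#' @param expr genes x samples matrix.
#' @param labels per-sample pattern labels, aligned with columns (or named
#'   by sample id). Each level needs >= 3 samples.
#' @param fdr_threshold BH-adjusted significance threshold (default 0.05).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return list of class `deg_result`: `contrasts` (per-pair data.frame
#'   with `gene`, `statistic`, `p`, `fdr`), `significant` (per-pair gene
#'   vectors), `intersection`.
#' @export
cluster_degs <- function(expr, labels, fdr_threshold = 0.05,
                         test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  labels <- as.character(labels)
  if (length(labels) != ncol(expr))
    abort_icp("labels do not match the number of samples")
  lev <- sort(unique(labels))
  if (length(lev) < 2L) abort_icp("need >= 2 pattern labels")
  sizes <- table(labels)
  if (any(sizes < 3L))
    abort_icp("pattern(s) with < 3 samples: ",
              paste(names(sizes)[sizes < 3L], collapse = ", "))

  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  contrasts <- list(); significant <- list()
  for (pr in pairs) {
    x1 <- expr[, labels == pr[1L], drop = FALSE]
    x2 <- expr[, labels == pr[2L], drop = FALSE]
    if (test == "welch") {
      res <- welch_rows(x1, x2)
    } else {
      res <- data.frame(t(apply(expr, 1L, function(v) {
        w <- stats::wilcox.test(v[labels == pr[1L]], v[labels == pr[2L]],
                                exact = FALSE)
        c(statistic = unname(w$statistic), p = w$p.value)
      })))
      names(res) <- c("statistic", "p")
    }
    res$fdr <- stats::p.adjust(res$p, method = "BH")
    tab <- data.frame(gene = rownames(expr), res, row.names = NULL,
                      stringsAsFactors = FALSE)
    key <- paste(pr, collapse = "_vs_")
    contrasts[[key]] <- tab
    significant[[key]] <- tab$gene[!is.na(tab$fdr) &
                                     tab$fdr < fdr_threshold]
  }
  structure(list(contrasts = contrasts, significant = significant,
                 intersection = Reduce(intersect, significant),
                 fdr_threshold = fdr_threshold, test = test),
            class = "deg_result")
}

#' PCA-based immune checkpoint score (ICscore)
#'
#' Signature genes are z-scored and a PCA is fit over samples; each
#' sample's ICscore is the sum of its coordinates on the first two
#' components. Sign indeterminacy is resolved by orienting each component
#' so that the sum of its gene loadings is <= 0: higher mean signature
#' expression then drives the score down, making low ICscore the
#' immune-hot end of the scale.
#'
#' @param expr genes x samples matrix.
#' @param signature_genes gene symbols; genes absent from the matrix are
#'   dropped with a warning, >= 2 usable (non-constant) genes required.
#' @return list of class `icscore_result`: `score` (named per-sample),
#'   `model` (genes, per-gene mean/sd, oriented 2-column rotation,
#'   explained variance fractions).
#' @export
derive_icscore <- function(expr, signature_genes) {
  present <- intersect(signature_genes, rownames(expr))
  if (length(present) < length(unique(signature_genes)))
    warning(length(unique(signature_genes)) - length(present),
            " signature gene(s) missing from the matrix, dropped")
  if (length(present) < 2L) abort_icp("need >= 2 usable signature genes")
  std <- standardize_rows(expr[present, , drop = FALSE], warn = TRUE)
  z <- std$z
  if (nrow(z) < 2L)
    abort_icp("need >= 2 signature genes with nonzero variance")
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  flip <- colSums(rot) > 0
  rot[, flip] <- -rot[, flip]
  coords <- t(z) %*% rot
  score <- rowSums(coords)
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  model <- list(genes = rownames(z), mean = std$mean, sd = std$sd,
                rotation = rot, explained = explained)
  structure(list(score = score, model = model), class = "icscore_result")
}

#' Score new samples through a fitted signature model
#'
#' Projects samples onto the stored (sign-oriented) rotation using the
#' stored per-gene standardization; scoring samples that were part of the
#' fit reproduces their original ICscore.
#'
#' @param model the `model` element of an `icscore_result`.
#' @param expr genes x samples matrix containing the model's genes.
#' @return named per-sample score vector.
#' @export
score_samples <- function(model, expr) {
  miss <- setdiff(model$genes, rownames(expr))
  if (length(miss)) abort_icp("matrix lacks model gene(s): ",
                              paste(utils::head(miss, 5L), collapse = ", "))
  z <- (expr[model$genes, , drop = FALSE] - model$mean) / model$sd
  rowSums(t(z) %*% model$rotation)
}

# two-group standardized log-rank statistic (O - E) / sqrt(V) for
# membership vector `in_group` (group 1 = TRUE)
logrank_z <- function(times, events, in_group) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]; g_s <- in_group[ord]
  n <- length(t_s)
  ev_times <- unique(t_s[e_s == 1])
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- t_s >= t
    n_all <- sum(at_risk)
    n1 <- sum(at_risk & g_s)
    dying <- t_s == t & e_s == 1
    d <- sum(dying)
    d1 <- sum(dying & g_s)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n_all
    if (n_all > 1)
      v <- v + d * (n1 / n_all) * (1 - n1 / n_all) * (n_all - d) / (n_all - 1)
  }
  if (v <= 0) return(NA_real_)
  (o1 - e1) / sqrt(v)
}

#' Survival-optimal dichotomization of a score
#'
#' Maximally selected log-rank cutpoint: candidate cutpoints are the
#' midpoints between consecutive sorted unique scores whose induced low /
#' high groups both hold at least `minprop` of the samples; the chosen
#' cutpoint maximizes the absolute standardized two-group log-rank
#' statistic, ties broken toward the candidate nearest the median score.
#'
#' @param scores named per-sample score vector.
#' @param times,events survival times (> 0) and event indicators (0/1)
#'   aligned with `scores`.
#' @param minprop minimum group proportion in (0, 0.5) (default 0.1).
#' @return list: `cutpoint`, `groups` (factor `"low"`/`"high"`, low =
#'   score <= cutpoint), `statistic` (|z| at the optimum), `scan`
#'   (data.frame of candidates and their z).
#' @export
dichotomize_by_cutpoint <- function(scores, times, events, minprop = 0.1) {
  if (minprop <= 0 || minprop >= 0.5) abort_icp("minprop must be in (0, 0.5)")
  n <- length(scores)
  if (length(times) != n || length(events) != n)
    abort_icp("scores and survival data differ in length")
  if (n < 10L) abort_icp("need >= 10 samples for the cutpoint search")
  u <- sort(unique(scores))
  if (length(u) < 2L) abort_icp("all scores equal: no candidate cutpoints")
  cand <- (u[-1L] + u[-length(u)]) / 2
  n_low <- vapply(cand, function(c) sum(scores <= c), 0L)
  ok <- n_low >= minprop * n & (n - n_low) >= minprop * n
  cand <- cand[ok]
  if (!length(cand)) abort_icp("no candidate cutpoint satisfies minprop")
  has_events <- vapply(cand, function(c)
    sum(events[scores <= c]) > 0 && sum(events[scores > c]) > 0, TRUE)
  if (!any(has_events))
    abort_icp("no candidate cutpoint has events on both sides")
  z <- vapply(cand, function(c) logrank_z(times, events, scores <= c),
              0)
  absz <- abs(z)
  best <- which(absz == max(absz, na.rm = TRUE))
  if (length(best) > 1L) {
    med <- stats::median(scores)
    best <- best[which.min(abs(cand[best] - med))]
  }
  cut <- cand[best]
  groups <- factor(ifelse(scores <= cut, "low", "high"),
                   levels = c("low", "high"))
  names(groups) <- names(scores)
  list(cutpoint = cut, groups = groups, statistic = absz[best],
       scan = data.frame(cutpoint = cand, z = z))
}
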