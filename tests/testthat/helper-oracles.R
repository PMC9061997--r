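# Independent reference implementations used as oracles. Deliberately
# naive (loops, enumeration, brute-force scans) and kept separate from the
# package's code paths.

# ssGSEA walk by direct summation of the cumulative-difference series
oracle_ssgsea <- function(x, set_genes, alpha) {
  genes <- names(x)
  r <- rank(x, ties.method = "average")
  ord <- order(-x, seq_along(x))
  n <- length(x)
  inset <- genes[ord] %in% set_genes
  r <- unname(r)
  w_tot <- sum(r[ord][inset]^alpha)
  n_out <- sum(!inset)
  es <- 0; p_in <- 0; p_out <- 0
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + r[ord][i]^alpha / w_tot
    else if (n_out > 0) p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}

# sample PCA coordinates from a full eigendecomposition of the
# uncentered gene crossproduct (matches prcomp(t(z), center = FALSE))
oracle_pca_coords <- function(z, d) {
  m <- t(z)                       # samples x genes
  eig <- eigen(crossprod(m), symmetric = TRUE)
  coords <- m %*% eig$vectors[, seq_len(d), drop = FALSE]
  list(coords = coords, values = eig$values)
}

# Benjamini-Hochberg by the step-up formula min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[ord[i]] <- min(1, min(p[ord[js]] * m / js))
  }
  adj
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (point-probability method)
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# distance correlation from explicitly double-centered distance matrices,
# elementwise loops
oracle_dcor <- function(x, y) {
  n <- length(x)
  a <- outer(x, x, function(u, v) abs(u - v))
  b <- as.matrix(stats::dist(cbind(y)))
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    A[j, k] <- a[j, k] - mean(a[j, ]) - mean(a[, k]) + mean(a)
    B[j, k] <- b[j, k] - mean(b[j, ]) - mean(b[, k]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  sqrt(max(dcov2, 0)) / (dvx * dvy)^(1 / 4)
}

# exact permutation log-rank p over all relabelings preserving group sizes
oracle_logrank_perm <- function(times, events, groups) {
  g1 <- which(groups == unique(groups)[1])
  n <- length(times)
  stat <- function(idx) {
    g <- rep("b", n); g[idx] <- "a"
    survival::survdiff(survival::Surv(times, events) ~ g)$chisq
  }
  obs <- stat(g1)
  all_sets <- utils::combn(n, length(g1), simplify = FALSE)
  perm <- vapply(all_sets, stat, 0)
  mean(perm >= obs - 1e-9)
}

# tie-free Cox partial log-likelihood for a single covariate
oracle_partial_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# exhaustive maximally selected log-rank scan via survdiff
oracle_cutpoint_scan <- function(scores, times, events, minprop) {
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  n <- length(scores)
  keep <- vapply(cand, function(c) {
    nl <- sum(scores <= c)
    nl >= minprop * n && (n - nl) >= minprop * n
  }, TRUE)
  cand <- cand[keep]
  chi <- vapply(cand, function(c) {
    g <- scores <= c
    if (sum(events[g]) == 0 && sum(events[!g]) == 0) return(NA_real_)
    survival::survdiff(survival::Surv(times, events) ~ g)$chisq
  }, 0)
  best <- which(chi == max(chi, na.rm = TRUE))
  if (length(best) > 1)
    best <- best[which.min(abs(cand[best] - stats::median(scores)))]
  list(cutpoint = cand[best], chisq = chi[best], candidates = cand,
       chisq_all = chi)
}

# small default cohort variants used across tests
small_sim <- function(seed = 1L, ...) {
  sim_config(n_per_pattern = c(A = 30L, B = 30L, C = 30L),
             n_background_genes = 400L, n_signature_genes = 120L,
             n_immune_sets = 8L, immune_set_size = 15L,
             n_neutral_sets = 1L, seed = seed, ...)
}
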