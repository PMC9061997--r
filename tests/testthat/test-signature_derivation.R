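test_that("BH adjustment follows the step-up formula", {
  # worked example: [0.01 0.02 0.03 0.04] -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(40)
  p <- runif(50)
  expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
})

test_that("DEG contrasts control discoveries under the global null", {
  set.seed(41)
  m <- 1000; n_per <- 12
  hits <- vapply(1:60, function(i) {
    x <- matrix(rnorm(m * 2 * n_per), m,
                dimnames = list(sprintf("G%04d", 1:m), NULL))
    colnames(x) <- sprintf("S%02d", 1:(2 * n_per))
    labels <- rep(c("A", "B"), each = n_per)
    res <- cluster_degs(x, labels, fdr_threshold = 0.05)
    length(res$significant[[1]]) > 0
  }, TRUE)
  # any-discovery rate under the global null stays near the FDR level
  expect_lte(mean(hits), 0.15)
})

test_that("planted shifts are recovered and intersection is a subset", {
  co <- simulate_cohort(small_sim(seed = 42))
  res <- cluster_degs(co$expression, co$truth$pattern)
  planted <- co$truth$signature_genes
  found_ac <- intersect(planted, res$significant[["A_vs_C"]])
  expect_gt(length(found_ac) / length(planted), 0.9)
  for (s in res$significant) {
    expect_true(all(res$intersection %in% s))
  }
  for (tab in res$contrasts) {
    expect_true(all(tab$fdr >= tab$p - 1e-12, na.rm = TRUE))
    expect_true(all(tab$fdr <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("labels with too few samples are rejected", {
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:10)))
  expect_error(cluster_degs(x, c(rep("A", 8), "B", "B")), "< 3")
})

test_that("ICscore equals PC1+PC2 coordinates from a brute-force eigensolver", {
  set.seed(43)
  x <- matrix(rnorm(500), 10, 50,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:50)))
  ic <- derive_icscore(x, rownames(x))
  z <- t(scale(t(x)))
  oracle <- oracle_pca_coords(z, 2)
  # apply the stated sign rule to the oracle loadings
  m <- t(z)
  eig <- eigen(crossprod(m), symmetric = TRUE)
  rot <- eig$vectors[, 1:2]
  flip <- colSums(rot) > 0
  rot[, flip] <- -rot[, flip]
  oracle_score <- rowSums(m %*% rot)
  expect_equal(unname(ic$score), unname(oracle_score), tolerance = 1e-8)
  # sign convention: loading sums are <= 0
  expect_true(all(colSums(ic$model$rotation) <= 1e-12))
})

test_that("two perfectly correlated genes collapse to the PC1 coordinate", {
  set.seed(44)
  v <- rnorm(30)
  x <- rbind(G1 = v, G2 = 2 * v + 1)
  colnames(x) <- paste0("S", 1:30)
  ic <- derive_icscore(x, c("G1", "G2"))
  z <- t(scale(t(x)))
  pc1 <- prcomp(t(z), center = FALSE)$x[, 1]
  if (sum(prcomp(t(z), center = FALSE)$rotation[, 1]) > 0) pc1 <- -pc1
  expect_equal(unname(ic$score), unname(pc1), tolerance = 1e-8)
})

test_that("ICscore is invariant to gene and sample order", {
  set.seed(45)
  x <- matrix(rnorm(400), 20, 20,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:20)))
  ic <- derive_icscore(x, rownames(x))
  ic_g <- derive_icscore(x[sample(20), ], rownames(x))
  expect_equal(ic$score, ic_g$score, tolerance = 1e-9)
  perm <- sample(20)
  ic_s <- derive_icscore(x[, perm], rownames(x))
  expect_equal(abs(unname(ic_s$score)), abs(unname(ic$score[perm])),
               tolerance = 1e-9)
})

test_that("a stored model scores held-in samples identically", {
  set.seed(46)
  x <- matrix(rnorm(600), 12, 50,
              dimnames = list(paste0("G", 1:12), paste0("S", 1:50)))
  ic <- derive_icscore(x, rownames(x))
  rescored <- score_samples(ic$model, x)
  expect_equal(rescored, ic$score, tolerance = 1e-12)
})

test_that("missing and degenerate signature genes are handled", {
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:10)))
  expect_warning(ic <- derive_icscore(x, c(rownames(x), "GHOST")), "missing")
  expect_equal(length(ic$score), 10L)
  expect_error(derive_icscore(x, "G1"), ">= 2")
})

test_that("perfectly separating scores cut between the two values", {
  scores <- setNames(c(0, 0, 0, 0, 0, 10, 10, 10, 10, 10),
                     paste0("S", 1:10))
  times <- c(20, 22, 24, 26, 28, 1, 2, 3, 4, 5)
  events <- c(0, 0, 1, 0, 1, 1, 1, 1, 1, 1)
  out <- dichotomize_by_cutpoint(scores, times, events, minprop = 0.1)
  expect_gt(out$cutpoint, 0)
  expect_lt(out$cutpoint, 10)
  expect_equal(unname(out$groups), factor(rep(c("low", "high"), each = 5),
                                          levels = c("low", "high")))
})

test_that("the chosen cutpoint matches an exhaustive survdiff scan", {
  set.seed(47)
  for (rep in 1:3) {
    n <- 60
    scores <- setNames(rnorm(n), paste0("S", 1:n))
    s <- simulate_survival(0.6 * scores, lambda0 = 0.05, censor_rate = 0.2)
    out <- dichotomize_by_cutpoint(scores, s$os_time, s$os_event,
                                   minprop = 0.1)
    oracle <- oracle_cutpoint_scan(scores, s$os_time, s$os_event, 0.1)
    expect_equal(out$cutpoint, oracle$cutpoint)
    expect_equal(out$statistic^2, oracle$chisq, tolerance = 1e-9)
  }
})

test_that("all-equal scores are an error", {
  scores <- setNames(rep(1, 12), paste0("S", 1:12))
  expect_error(dichotomize_by_cutpoint(scores, 1:12, rep(1, 12)),
               "no candidate|equal")
})
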