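two_blobs <- function(n_per = 20, sep = 10, g = 40, seed = 1) {
  set.seed(seed)
  x <- cbind(matrix(rnorm(g * n_per), g),
             matrix(rnorm(g * n_per, sep * rep(c(1, -1), length.out = g)), g))
  dimnames(x) <- list(sprintf("G%02d", 1:g), sprintf("S%02d", 1:(2 * n_per)))
  list(x = x, truth = rep(1:2, each = n_per))
}

test_that("well-separated blobs give a near-0/1 consensus and perfect ARI", {
  d <- two_blobs()
  res <- consensus_cluster(d$x, k = 2, n_resamples = 200, seed = 3)
  M <- res$consensus
  within <- M[d$truth == 1, d$truth == 1]
  between <- M[d$truth == 1, d$truth == 2]
  expect_gte(min(within[upper.tri(within)]), 0.99)
  expect_lte(max(between), 0.01)
  expect_equal(adjusted_rand_index(res$assignments, d$truth), 1)
})

test_that("consensus matrix is a valid symmetric proportion matrix", {
  d <- two_blobs(n_per = 15, sep = 1.5)
  res <- consensus_cluster(d$x, k = 3, n_resamples = 50, seed = 5)
  M <- res$consensus
  expect_true(all(M >= 0 & M <= 1))
  expect_identical(M, t(M))
  expect_true(all(diag(M) == 1))
  expect_true(all(table(res$assignments) > 0))
  expect_setequal(unique(res$assignments), 1:3)
})

test_that("duplicated sample columns always co-cluster", {
  d <- two_blobs(n_per = 10)
  x <- cbind(d$x, dup = d$x[, 1])
  colnames(x)[ncol(x)] <- "dup"
  res <- consensus_cluster(x, k = 2, n_resamples = 150, seed = 6)
  expect_equal(res$consensus["S01", "dup"], 1)
})

test_that("same seed reproduces the consensus matrix exactly", {
  d <- two_blobs(n_per = 12, sep = 2)
  r1 <- consensus_cluster(d$x, k = 2, n_resamples = 40, seed = 7)
  r2 <- consensus_cluster(d$x, k = 2, n_resamples = 40, seed = 7)
  expect_identical(r1$consensus, r2$consensus)
  expect_identical(r1$assignments, r2$assignments)
})

test_that("full item fraction with a deterministic clusterer gives 0/1 entries", {
  d <- two_blobs(n_per = 12, sep = 2)
  res <- consensus_cluster(d$x, k = 2, n_resamples = 10, item_fraction = 1,
                           seed = 8)
  expect_true(all(res$consensus %in% c(0, 1)))
})

test_that("degenerate k and resample settings are rejected", {
  d <- two_blobs(n_per = 5)
  expect_error(consensus_cluster(d$x, k = 10), "smaller")
  expect_error(consensus_cluster(d$x, k = 1), ">= 2")
  expect_error(consensus_cluster(d$x, k = 2, n_resamples = 1), "resamples")
})

test_that("PAC matches direct counting of ambiguous entries", {
  fake_result <- function(M, k) {
    structure(list(k = k, consensus = M,
                   assignments = rep(1:k, length.out = nrow(M)),
                   n_resamples = 10, item_fraction = 0.8),
              class = "consensus_result")
  }
  n <- 10
  crisp <- matrix(rep(c(0, 1), length.out = n * n), n, n)
  crisp <- (crisp + t(crisp)) / 2; crisp[crisp == 0.5] <- 1; diag(crisp) <- 1
  half <- matrix(0, n, n)
  half[upper.tri(half)] <- rep(c(0.5, 0), length.out = sum(upper.tri(half)))
  half <- half + t(half); diag(half) <- 1

  res <- list(fake_result(crisp, 2), fake_result(half, 3),
              fake_result(crisp, 4))
  ks <- select_k(res)
  expect_equal(unname(ks$pac[c("2", "4")]), c(0, 0))
  expect_equal(unname(ks$pac["3"]),
               mean(half[upper.tri(half)] > 0.1 & half[upper.tri(half)] <= 0.9))
  expect_equal(unname(ks$pac["3"]), 0.5, tolerance = 0.06)
  expect_true(is.na(ks$delta_area[1]))
  expect_equal(ks$chosen_k, 2)  # tie between k=2 and k=4 broken downward
})

test_that("select_k demands a grid of >= 3 consecutive k values", {
  d <- two_blobs(n_per = 10)
  r2 <- consensus_cluster(d$x, 2, 30, seed = 1)
  r4 <- consensus_cluster(d$x, 4, 30, seed = 1)
  expect_error(select_k(list()), "empty")
  expect_error(select_k(list(r2, r4)), "consecutive")
})

test_that("PAC is non-increasing as planted separation grows", {
  pac_at <- function(sep) {
    d <- two_blobs(n_per = 15, sep = sep, seed = 10)
    r <- consensus_cluster(d$x, 2, n_resamples = 80, seed = 11)
    mean(r$consensus[upper.tri(r$consensus)] > 0.1 &
           r$consensus[upper.tri(r$consensus)] <= 0.9)
  }
  pacs <- vapply(c(0.05, 0.6, 6), pac_at, 0)
  expect_true(all(diff(pacs) <= 1e-9))
})

test_that("PCA embedding matches a brute-force eigendecomposition", {
  set.seed(20)
  x <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:20)))
  emb <- pca_embed(x, d = 3)
  z <- t(scale(t(x)))
  oracle <- oracle_pca_coords(z, 3)
  for (j in 1:3) {
    expect_equal(abs(unname(emb$coordinates[, j])),
                 abs(unname(oracle$coords[, j])), tolerance = 1e-8)
  }
  expect_true(all(diff(emb$explained) <= 1e-12))
  expect_lt(abs(sum(crossprod(emb$rotation)[upper.tri(diag(3))])), 1e-8)
})

test_that("rank-1 input loads almost all variance on the first component", {
  u <- rnorm(12); v <- rnorm(30)
  x <- outer(u, v) + 1e-8 * matrix(rnorm(360), 12, 30)
  dimnames(x) <- list(paste0("G", 1:12), paste0("S", 1:30))
  emb <- pca_embed(x, 2)
  expect_gte(emb$explained[1], 1 - 1e-6)
})

test_that("permuting samples permutes coordinates without changing values", {
  set.seed(21)
  x <- matrix(rnorm(150), 5, 30,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:30)))
  emb <- pca_embed(x, 2)
  perm <- sample(30)
  emb_p <- pca_embed(x[, perm], 2)
  expect_equal(abs(unname(emb_p$coordinates)),
               abs(unname(emb$coordinates[perm, ])), tolerance = 1e-9)
})

test_that("constant genes are dropped with a warning before embedding", {
  x <- rbind(matrix(rnorm(40), 2, 20), 0)
  dimnames(x) <- list(c("G1", "G2", "FLAT"), paste0("S", 1:20))
  expect_warning(emb <- pca_embed(x, 2), "constant")
  expect_false("FLAT" %in% rownames(emb$rotation))
})

test_that("pattern labels canonicalize to A/B/C by mean panel expression", {
  x <- cbind(matrix(5, 4, 3), matrix(1, 4, 3), matrix(3, 4, 3))
  dimnames(x) <- list(paste0("G", 1:4), paste0("S", 1:9))
  assign <- setNames(rep(c(1, 2, 3), each = 3), colnames(x))
  lab <- canonicalize_patterns(assign, x)
  expect_equal(unname(lab[1:3]), rep("A", 3))   # highest expression
  expect_equal(unname(lab[4:6]), rep("C", 3))   # lowest
  expect_equal(unname(lab[7:9]), rep("B", 3))
})
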