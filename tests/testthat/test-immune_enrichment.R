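test_that("the single-top-gene walk reproduces the closed-form score", {
  x <- matrix(c(5, 4, 3, 2, 1), 5, 1,
              dimnames = list(paste0("G", 1:5), "S1"))
  sc <- ssgsea(x, list(top = "G1"), alpha = 1)
  # P_in jumps to 1 at position 1; P_out climbs (i-1)/4: ES = 2.5
  expect_equal(unname(sc["top", "S1"]), 2.5)
})

test_that("walk scores match the direct-summation oracle on random toys", {
  set.seed(30)
  for (rep in 1:5) {
    n_genes <- sample(5:50, 1)
    x <- matrix(rnorm(n_genes * 3), n_genes, 3,
                dimnames = list(paste0("G", seq_len(n_genes)),
                                paste0("S", 1:3)))
    set_genes <- sample(rownames(x), sample(2:min(8, n_genes - 1), 1))
    alpha <- sample(c(0, 0.25, 1), 1)
    sc <- ssgsea(x, list(s = set_genes), alpha = alpha)
    for (s in 1:3) {
      expect_equal(unname(sc["s", s]),
                   oracle_ssgsea(x[, s], set_genes, alpha),
                   tolerance = 1e-10)
    }
  }
})

test_that("scores are invariant to strictly monotone transforms", {
  set.seed(31)
  x <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:3)))
  sets <- list(a = paste0("G", 1:5), b = paste0("G", c(2, 9, 17)))
  s1 <- ssgsea(x, sets)
  s2 <- ssgsea(exp(x), sets)
  expect_equal(s1, s2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a set covering every gene scores from the in-set walk alone", {
  x <- matrix(c(3, 2, 1), 3, 1,
              dimnames = list(c("A", "B", "C"), "S1"))
  sc <- ssgsea(x, list(all = c("A", "B", "C")), alpha = 1)
  r <- c(3, 2, 1)
  expect_equal(unname(sc["all", 1]), sum(cumsum(r) / sum(r)))
})

test_that("non-overlapping sets are dropped with a warning", {
  x <- matrix(rnorm(20), 10, 2,
              dimnames = list(paste0("G", 1:10), c("S1", "S2")))
  expect_warning(sc <- ssgsea(x, list(ok = "G1", gone = "ZZZ")), "gone")
  expect_equal(rownames(sc), "ok")
  expect_equal(attr(sc, "dropped"), "gone")
})

test_that("minmax normalization puts every set row on [0, 1] attained", {
  set.seed(32)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
  sc <- ssgsea(x, list(a = paste0("G", 1:4), b = paste0("G", 5:9)),
               normalize = "minmax")
  expect_equal(unname(apply(sc, 1, min)), c(0, 0))
  expect_equal(unname(apply(sc, 1, max)), c(1, 1))
})

test_that("ESTIMATE-style scores satisfy the additive identity", {
  set.seed(33)
  x <- matrix(rnorm(300), 30, 10,
              dimnames = list(paste0("G", 1:30), paste0("S", 1:10)))
  es <- estimate_scores(x, stromal_set = paste0("G", 1:5),
                        immune_set = paste0("G", 6:12))
  expect_equal(es$ESTIMATEScore, es$StromalScore + es$ImmuneScore)
  expect_error(estimate_scores(x, stromal_set = paste0("G", 1:5),
                               immune_set = "NOPE"), "immune")
})

test_that("planted immune-hot samples score higher on immune sets", {
  co <- simulate_cohort(small_sim(seed = 34))
  es <- estimate_scores(co$expression,
                        co$gene_sets$STROMAL_SIGNATURE,
                        co$gene_sets$IMMUNE_SIGNATURE)
  pat <- co$truth$pattern[es$sample_id]
  expect_gt(mean(es$ImmuneScore[pat == "A"]),
            mean(es$ImmuneScore[pat == "C"]))
})

test_that("most immune-cell sets score higher in pattern A than C", {
  co <- simulate_cohort(small_sim(seed = 35))
  cell_sets <- co$gene_sets[setdiff(names(co$gene_sets),
                                    c("IMMUNE_SIGNATURE",
                                      "STROMAL_SIGNATURE"))]
  sc <- ssgsea(co$expression, cell_sets)
  pat <- co$truth$pattern[colnames(sc)]
  diff_ac <- rowMeans(sc[, pat == "A"]) - rowMeans(sc[, pat == "C"])
  expect_gt(mean(diff_ac > 0), 0.5)
})

test_that("spearman correlation is monotone-invariant with exact rho 1", {
  x <- sort(rnorm(20))
  out <- correlate(x, exp(x), "spearman")
  expect_equal(out$statistic, 1)
  expect_equal(out$p_value, 0)
})

test_that("distance correlation matches the double-centering oracle", {
  set.seed(36)
  x <- c(0.2, -1.4, 2.2, 0.9)
  y <- c(1.1, 0.3, -0.7, 2.5)
  out <- correlate(x, y, "distance", n_perm = 99, seed = 1)
  expect_equal(out$statistic, oracle_dcor(x, y), tolerance = 1e-12)
  x2 <- rnorm(25); y2 <- rnorm(25)
  out2 <- correlate(x2, y2, "distance", n_perm = 99, seed = 2)
  expect_equal(out2$statistic, oracle_dcor(x2, y2), tolerance = 1e-12)
})

test_that("independent inputs give small distance correlation", {
  set.seed(37)
  x <- rnorm(2000); y <- rnorm(2000)
  out <- correlate(x, y, "distance", n_perm = 30, seed = 3)
  expect_lt(out$statistic, 0.1)
  expect_gt(out$p_value, 0.05)
})

test_that("constant vectors yield missing statistics with a warning", {
  expect_warning(out <- correlate(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(out$statistic))
  expect_error(correlate(1:3, 1:3), ">= 4")
})
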