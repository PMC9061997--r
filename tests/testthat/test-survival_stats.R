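test_that("KM with no censoring is the empirical survival function", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$time, 1:4)
})

test_that("KM with all observations censored stays at 1", {
  km <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km$surv == 1))
})

test_that("KM handles censoring by the product-limit rule", {
  # hand oracle: S(1) = 2/3; censor at 2; S(3) = 2/3 * (1 - 1/1) = 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_survival_at(km, 1), 2 / 3)
  expect_equal(km_survival_at(km, 3), 0)
  expect_equal(km_survival_at(km, 0.5), 1)
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank of identical groups is exactly null", {
  times <- c(1, 2, 3, 4, 1, 2, 3, 4)
  events <- rep(1, 8)
  out <- logrank_test(times, events, rep(c("a", "b"), each = 4))
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1)
  expect_equal(sum(out$observed - out$expected), 0, tolerance = 1e-12)
})

test_that("log-rank p agrees with the exact permutation oracle on a toy", {
  times <- 1:6
  events <- rep(1, 6)
  groups <- rep(c("A", "B"), 3)  # A: 1,3,5; B: 2,4,6
  out <- logrank_test(times, events, groups)
  p_perm <- oracle_logrank_perm(times, events, groups)
  # chi-square approximation vs exact permutation within MC-free enumeration
  expect_lt(abs(out$p_value - p_perm), 0.25)
  expect_gt(out$p_value, 0.05)  # no real difference in this toy
  # O - E bookkeeping sums to zero
  expect_equal(sum(out$observed - out$expected), 0, tolerance = 1e-9)
})

test_that("log-rank type-I error is calibrated at the nominal level", {
  set.seed(50)
  n_sims <- 1000
  rejections <- vapply(seq_len(n_sims), function(i) {
    times <- rexp(90, 0.1)
    events <- rbinom(90, 1, 0.8)
    groups <- rep(c("a", "b", "c"), each = 30)
    logrank_test(times, events, groups)$p_value < 0.05
  }, TRUE)
  se <- sqrt(0.05 * 0.95 / n_sims)
  expect_lt(abs(mean(rejections) - 0.05), 3 * se)
})

test_that("Cox score test at beta 0 equals the two-group log-rank statistic", {
  set.seed(51)
  times <- round(rexp(40, 0.1), 6)  # tie-free
  events <- rbinom(40, 1, 0.7); events[1] <- 1
  grp <- rep(c(0, 1), 20)
  d <- data.frame(os_time = times, os_event = events, grp = grp)
  fit <- cox_fit(d, "grp")
  lr <- logrank_test(times, events, grp)
  expect_equal(unname(fit$score_test["test"]), lr$statistic,
               tolerance = 1e-6)
})

test_that("Efron and Breslow agree exactly on tie-free data", {
  set.seed(52)
  d <- data.frame(os_time = rexp(50, 0.1), os_event = rbinom(50, 1, 0.8),
                  x = rnorm(50))
  d$os_event[1] <- 1
  fe <- cox_fit(d, "x", ties = "efron")
  fb <- cox_fit(d, "x", ties = "breslow")
  expect_equal(fe$coef$beta, fb$coef$beta, tolerance = 1e-9)
})

test_that("constant and collinear covariates are rejected by name", {
  d <- data.frame(os_time = rexp(20, 0.1), os_event = rep(1, 20),
                  flat = 1, x = rnorm(20))
  d$x2 <- 2 * d$x
  expect_error(cox_fit(d, c("flat", "x")), "flat")
  expect_error(cox_fit(d, c("x", "x2")), "collinear|rank")
})

test_that("Cox CI covers the true hazard ratio at the nominal rate", {
  set.seed(53)
  n_sims <- 500
  beta_true <- 0.5
  covered <- vapply(seq_len(n_sims), function(i) {
    x <- rnorm(120)
    s <- simulate_survival(beta_true * x, lambda0 = 0.05, censor_rate = 0.2)
    d <- data.frame(os_time = s$os_time, os_event = s$os_event, x = x)
    fit <- cox_fit(d, "x")
    fit$coef$hr_lower[1] <= exp(beta_true) &&
      exp(beta_true) <= fit$coef$hr_upper[1]
  }, TRUE)
  se <- sqrt(0.95 * 0.05 / n_sims)
  expect_lt(abs(mean(covered) - 0.95), 3.5 * se)
})

test_that("the univariate screen labels a planted protective gene favorable", {
  set.seed(54)
  n <- 300
  hits <- vapply(1:20, function(i) {
    g <- rnorm(n)
    s <- simulate_survival(-0.7 * g, lambda0 = 0.05, censor_rate = 0.2)
    expr <- matrix(c(g, rnorm(n)), 2, n, byrow = TRUE,
                   dimnames = list(c("PROT", "NULL1"), paste0("S", 1:n)))
    cl <- data.frame(sample_id = colnames(expr), os_time = s$os_time,
                     os_event = s$os_event)
    out <- univariate_screen(expr, cl)
    out$direction[out$gene == "PROT"] == "favorable"
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("constant genes give missing screen rows with a warning", {
  expr <- matrix(c(rep(1, 10), rnorm(10)), 2, 10, byrow = TRUE,
                 dimnames = list(c("FLAT", "OK"), paste0("S", 1:10)))
  cl <- data.frame(sample_id = colnames(expr), os_time = rexp(10, 0.1) + 0.1,
                   os_event = rep(1, 10))
  expect_warning(out <- univariate_screen(expr, cl), "constant")
  expect_true(is.na(out$beta[out$gene == "FLAT"]))
  expect_false(is.na(out$beta[out$gene == "OK"]))
})

test_that("a balanced 2x2 table shows perfect independence", {
  a <- rep(c("x", "x", "y", "y"), 10)
  b <- rep(c("u", "v", "u", "v"), 10)
  out <- contingency_test(a, b)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$odds_ratio, 1)
})

test_that("Fisher p matches hypergeometric enumeration on a diagonal table", {
  a <- rep(c("m", "w"), each = 4)
  b <- rep(c("m", "w"), each = 4)
  out <- contingency_test(a, b)
  expect_equal(out$p_value, 2 / 70, tolerance = 1e-12)
  tab <- matrix(c(4, 0, 0, 4), 2, 2)
  expect_equal(oracle_fisher_2x2(tab), 2 / 70, tolerance = 1e-12)
  expect_equal(out$p_value, oracle_fisher_2x2(tab), tolerance = 1e-12)
})

test_that("larger tables fall back to Pearson chi-squared", {
  set.seed(55)
  a <- sample(c("p", "q", "r"), 120, replace = TRUE)
  b <- sample(c("u", "v"), 120, replace = TRUE)
  out <- contingency_test(a, b)
  expect_equal(out$method, "chisq")
  expect_equal(out$df, 2L)
  ref <- suppressWarnings(chisq.test(table(a, b), correct = FALSE))
  expect_equal(out$p_value, ref$p.value)
})

test_that("single-level factors are an error", {
  expect_error(contingency_test(rep("only", 10), rep(c("a", "b"), 5)),
               "levels")
})
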