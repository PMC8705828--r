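# exact small-sample statistics against enumeration oracles and the
# independent base-R implementations

test_that("Mann-Whitney exact p matches full rank enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)              # 2 of the 20 arrangements
  expect_equal(r$method, "exact")
  # identical multisets -> p ~ 1 (full overlap, ties force asymptotic)
  expect_gt(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.99)
  set.seed(23)
  for (i in 1:200) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(100, n1); y <- sample(100, n2)  # no ties
    while (length(intersect(x, y))) y <- sample(100, n2)
    expect_identical(mann_whitney(x, y)$p_value, oracle_mw_p(x, y))
  }
})

test_that("Mann-Whitney agrees with the base-R implementation", {
  set.seed(29)
  for (i in 1:50) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    ours <- mann_whitney(x, y)
    # compare like with like: the exact range here is combined n <= 12
    ref <- stats::wilcox.test(x, y, exact = ours$method == "exact",
                              correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # asymptotic branch with ties
  x <- c(rnorm(15), 1, 1, 2); y <- c(rnorm(18), 1, 2, 2)
  expect_equal(mann_whitney(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank exact p matches sign-pattern enumeration", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.0625)           # 2 / 2^5
  expect_equal(r$method, "exact")
  # symmetric pairs: p ~ 1
  expect_gte(wilcoxon_signed_rank(c(-3, 3, -2, 2, -1, 1, 5, -5,
                                    4, -4))$p_value, 0.9)
  set.seed(37)
  for (i in 1:200) {
    n <- sample(4:10, 1)
    d <- sample(c(-1, 1), n, replace = TRUE) * sample(100, n)
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_wsr_p(d),
                 tolerance = 1e-12)
  }
  # zero differences are dropped and recorded
  rz <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5))
  expect_equal(rz$n_zero, 2)
  expect_equal(rz$n_pairs, 5)
  all0 <- wilcoxon_signed_rank(rep(0, 6))
  expect_equal(all0$p_value, 1)
  expect_true(all0$flagged)
})

test_that("signed-rank agrees with the base-R implementation", {
  set.seed(41)
  for (i in 1:50) {
    d <- rnorm(sample(6:15, 1))
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 stats::wilcox.test(d)$p.value, tolerance = 1e-12)
  }
  d <- rnorm(40)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               stats::wilcox.test(d, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("binomial test sums the pmf exactly", {
  # null equal to the observed proportion: the mode is included -> p = 1
  expect_equal(binomial_proportion_test(21, 42, 0.5)$p_value, 1)
  set.seed(43)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binomial_proportion_test(k, n, p0)$p_value,
                 oracle_binom_p(k, n, p0), tolerance = 1e-12)
    expect_equal(binomial_proportion_test(k, n, p0)$p_value,
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-12)
  }
  # one-sided tails
  expect_equal(binomial_proportion_test(8, 10, 0.5,
                                        alternative = "greater")$p_value,
               sum(stats::dbinom(8:10, 10, 0.5)), tolerance = 1e-15)
  # degenerate nulls
  expect_equal(binomial_proportion_test(0, 10, 0)$p_value, 1)
  expect_equal(binomial_proportion_test(3, 10, 0)$p_value, 0)
})

test_that("the small-p convention reproduces the reported proportions", {
  cases <- data.frame(k = c(24, 13), n = c(42, 42),
                      p0 = c(10 / 27, 4 / 27),
                      reported_p = c(0.0098, 0.0073))
  rep <- binomial_convention_report(cases)
  expect_equal(rep$matches, c("small_p", "small_p"))
  expect_equal(round(rep$p_small_p, 4), c(0.0098, 0.0073))
})

test_that("KS statistic matches the ECDF oracle and compound rule holds", {
  set.seed(47)
  for (i in 1:200) {
    x <- rnorm(sample(10:40, 1))
    y <- rnorm(sample(10:40, 1), sample(c(0, 1), 1))
    r <- ks_compare(x, y)
    expect_equal(r$statistic, oracle_ks_d(x, y), tolerance = 1e-12)
    # both evaluate the asymptotic Kolmogorov distribution; base R's
    # series truncation differs in the last digits
    expect_equal(r$p_value,
                 stats::ks.test(x, y, exact = FALSE)$p.value,
                 tolerance = 1e-3)
  }
  x <- rnorm(30)
  r <- ks_compare(x, x)
  expect_equal(r$statistic, 0)
  expect_false(r$significant)
  # compound rule: D large but p above alpha is not significant
  r2 <- ks_compare(rnorm(12), rnorm(12, 0.5))
  if (r2$p_value >= 0.01) expect_false(r2$significant)
  # significant requires BOTH small p and D > 0.1
  big <- ks_compare(rnorm(300), rnorm(300, 2))
  expect_true(big$significant)
})

test_that("Spearman rho and exact permutation p match the oracle", {
  r <- spearman(1:7, 7:1)
  expect_equal(r$statistic, -1)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 2 / factorial(7), tolerance = 1e-12)
  set.seed(53)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    ours <- spearman(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(ours$statistic, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  # asymptotic branch against the t-approximation used by base R
  x <- rnorm(30); y <- rnorm(30)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(spearman(x, y)$statistic, unname(ref$estimate),
               tolerance = 1e-12)
  expect_error(spearman(1:4, 4:1), "n >= 5")
  expect_error(spearman(rep(1, 6), 1:6), "constant")
})

test_that("permuted pairs give rho centred on zero", {
  set.seed(59)
  rhos <- replicate(1000, spearman(rnorm(8), rnorm(8))$statistic)
  expect_lt(abs(mean(rhos)), 0.03)
})

test_that("exact modes reject at their attainable null level", {
  # discrete exact tests cannot reject at exactly 5%; the correct
  # property is that the empirical rate matches the attainable level
  # (largest achievable p <= 0.05) of the null distribution
  set.seed(61)
  n_sim <- 4000
  # Wilcoxon signed-rank, n = 10
  pmf <- slicephys:::.signrank_null(10)
  tot <- 10 * 11 / 2
  w_levels <- 0:floor(tot / 2)
  p_of_w <- vapply(w_levels, function(w)
    min(1, 2 * sum(pmf[seq_len(w + 1)])), 0)
  attain_w <- sum(2 * pmf[seq_len(max(which(p_of_w <= 0.05)))])
  rej <- mean(replicate(n_sim,
                        wilcoxon_signed_rank(rnorm(10))$p_value <= 0.05))
  expect_equal(rej, attain_w, tolerance = 0.012)
  # Mann-Whitney 5 vs 5
  rej_mw <- mean(replicate(n_sim,
                           mann_whitney(rnorm(5), rnorm(5))$p_value <= 0.05))
  u_all <- colSums(utils::combn(10, 5)) - 15
  p_all <- vapply(u_all, function(u)
    mean(abs(u_all - 12.5) >= abs(u - 12.5) - 1e-9), 0)
  attain_mw <- mean(p_all <= 0.05)
  expect_equal(rej_mw, attain_mw, tolerance = 0.012)
})
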