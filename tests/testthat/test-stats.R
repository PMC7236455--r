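test_that("2x2 Fisher equals the frozen hypergeometric-sum oracle", {
  # oracle (computed first, independently): margins rows (26,26), cols (15,37);
  # p = sum over a in 0..15 of dhyper(a,15,37,26) restricted to tables no more
  # likely than a = 3  ->  0.01283044
  r <- fisher_exact_2xk(rbind(c(3, 23), c(12, 14)))
  expect_equal(r$p_value, 0.01283044, tolerance = 1e-6)
  # and live cross-check against the same oracle recomputed here
  p_obs <- dhyper(3, 15, 37, 26)
  ps <- dhyper(0:15, 15, 37, 26)
  expect_equal(r$p_value, sum(ps[ps <= p_obs * (1 + 1e-12)]), tolerance = 1e-12)
})

test_that("balanced 2x2 tables give p = 1 and zero margins are degenerate", {
  expect_equal(fisher_exact_2xk(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  r0 <- fisher_exact_2xk(rbind(c(0, 0), c(5, 5)))
  expect_equal(r0$p_value, 1)
  expect_true(r0$degenerate)
  expect_error(fisher_exact_2xk(rbind(c(-1, 2), c(3, 4))),
               class = "cellloss_domain_error")
})

test_that("Freeman-Halton p agrees with fisher.test across random tables", {
  set.seed(21)
  for (i in 1:15) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(2 * k, 6), nrow = 2)
    tab[1, 1] <- tab[1, 1] + 1 # avoid all-zero margins
    r <- fisher_exact_2xk(tab)
    expect_equal(r$p_value, stats::fisher.test(tab)$p.value, tolerance = 1e-8,
                 info = paste(tab, collapse = ","))
  }
})

test_that("Fisher p is invariant under column permutation and row swap", {
  tab <- rbind(c(3, 3, 6, 12), c(23, 23, 20, 14))
  p0 <- fisher_exact_2xk(tab)$p_value
  expect_equal(fisher_exact_2xk(tab[, c(4, 2, 1, 3)])$p_value, p0)
  expect_equal(fisher_exact_2xk(tab[2:1, ])$p_value, p0)
})

test_that("enumerated table probabilities conserve mass", {
  for (tab in list(rbind(c(3, 3, 6, 12), c(23, 23, 20, 14)),
                   rbind(c(2, 5, 1), c(4, 0, 7)),
                   rbind(c(9, 1), c(2, 8)))) {
    expect_equal(sum(fisher_table_probabilities(tab)), 1, tolerance = 1e-9)
  }
})

test_that("making a 2x2 table more extreme never increases the Fisher p", {
  # hold margins (10,10) x (8,12); shift mass toward the diagonal
  ps <- vapply(4:8, function(a) {
    fisher_exact_2xk(rbind(c(a, 10 - a), c(8 - a, 2 + a)))$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("Wilcoxon rank-sum reproduces the full-enumeration example", {
  # x = 1,2,3 vs y = 4,5,6: W (Mann-Whitney U) = 0, the most extreme of the
  # 20 equally likely rank subsets -> two-sided exact p = 2 * 1/20 = 0.1
  r <- wilcoxon_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 0)
  expect_match(r$method, "exact")
})

test_that("degenerate paired Wilcoxon (all differences zero) gives p = 1", {
  r <- wilcoxon_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  expect_error(wilcoxon_test(1:3, 1:4, paired = TRUE),
               class = "cellloss_precondition_error")
  expect_error(wilcoxon_test(numeric(0), 1:3),
               class = "cellloss_precondition_error")
})

test_that("Wilcoxon agrees with wilcox.test on both branches", {
  set.seed(22)
  # exact branch, tie-free
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), 0.5)
    expect_equal(wilcoxon_test(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # paired exact branch
  for (i in 1:5) {
    x <- rnorm(8); y <- x + rnorm(8, 0.3)
    expect_equal(wilcoxon_test(x, y, paired = TRUE)$p_value,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # approximate branch vs wilcox.test's corrected normal approximation
  for (i in 1:5) {
    x <- rnorm(15); y <- rnorm(15, 0.6)
    expect_equal(wilcoxon_test(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("approximate and exact Wilcoxon branches agree closely at n = 15 vs 15", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15, runif(1, 0, 1))
    approx_p <- wilcoxon_test(x, y)$p_value
    exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("one-way ANOVA reproduces the hand ANOVA table", {
  # SSB = 6 (df 2), SSW = 6 (df 6) -> F = 3, p = P(F_{2,6} > 3) = 0.125
  r <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r$statistic, 3)
  expect_equal(r$p_value, 0.125)
})

test_that("ANOVA degenerate rules: zero within-group variance", {
  r1 <- anova_oneway(list(c(1, 1), c(1, 1)))
  expect_equal(r1$p_value, 1)
  expect_true(r1$degenerate)
  r2 <- anova_oneway(list(c(1, 1), c(2, 2)))
  expect_equal(r2$p_value, 0)
  expect_true(r2$degenerate)
  expect_error(anova_oneway(list(c(1, 2))), class = "cellloss_precondition_error")
})

test_that("ANOVA agrees with aov on random data, including a binary response", {
  set.seed(24)
  for (i in 1:8) {
    g <- factor(sample(letters[1:4], 40, replace = TRUE))
    y <- rnorm(40) + as.numeric(g) * 0.2
    r <- anova_oneway(split(y, g))
    ref <- summary(stats::aov(y ~ g))[[1]]
    expect_equal(r$statistic, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(r$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  # binary response vs 4-level factor: the covariate-screen usage shape
  y01 <- rbinom(60, 1, 0.3)
  g4 <- factor(sample(1:4, 60, replace = TRUE))
  r <- anova_oneway(split(y01, g4))
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

test_that("Spearman correlation matches the rank-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  expect_equal(spearman_correlation(x, x)$statistic, 1)
  expect_equal(spearman_correlation(x, -x)$statistic, -1)
  set.seed(25)
  for (i in 1:10) {
    a <- rnorm(10); b <- rnorm(10)
    r <- spearman_correlation(a, b)
    expect_equal(r$statistic, stats::cor(rank(a), rank(b)), tolerance = 1e-12)
    expect_equal(r$p_value,
                 stats::cor.test(a, b, method = "spearman", exact = FALSE)$p.value,
                 tolerance = 1e-10)
  }
  d <- spearman_correlation(rep(1, 5), rnorm(5))
  expect_true(d$degenerate)
})

test_that("pooled_mean weights subgroup means by size", {
  expect_equal(pooled_mean(c(2, 2), c(1, 3)), 2)
  expect_equal(pooled_mean(c(38, 42), c(0.08, 0.05)), (38 * 0.08 + 42 * 0.05) / 80)
})
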