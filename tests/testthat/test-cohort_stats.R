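test_that("summary-based ANOVA agrees exactly with the raw-data ANOVA", {
  set.seed(101)
  values <- c(stats::rnorm(12, 10, 2), stats::rnorm(16, 12, 2.5),
              stats::rnorm(8, 15, 3))
  groups <- rep(c("HC", "ET1", "ET2"), c(12, 16, 8))
  a_raw <- one_way_anova(values, groups)
  a_sum <- anova_from_summary(summarize_groups(values, groups))
  expect_equal(a_sum$value, a_raw$value, tolerance = 1e-10)
  expect_equal(a_sum$df, a_raw$df, tolerance = 0)
  expect_equal(a_sum$p_value, a_raw$p_value, tolerance = 1e-10)

  # equal group means give F = 0
  s0 <- group_summary(c("a", "b"), c(5, 5), c(1, 2), c(6, 7))
  expect_equal(anova_from_summary(s0)$value, 0, tolerance = 0)
})

test_that("summary t-test equals the raw pooled t-test and satisfies F = t^2", {
  set.seed(103)
  x <- stats::rnorm(16, 22.4, 17.9); y <- stats::rnorm(8, 36.1, 17.9)
  s <- summarize_groups(c(x, y), rep(c("ET1", "ET2"), c(16, 8)))
  tt <- t_from_summary(s)
  ht <- stats::t.test(x, y, var.equal = TRUE)
  # summarize_groups orders groups alphabetically (ET1 then ET2), matching x, y
  expect_equal(tt$value, unname(ht$statistic), tolerance = 1e-10)
  expect_equal(tt$p_value, ht$p.value, tolerance = 1e-10)
  expect_equal(tt$F, tt$value^2, tolerance = 1e-12)
  expect_identical(tt$F_df, c(1L, 22L))

  same <- group_summary(c("a", "b"), c(3, 3), c(1, 1), c(5, 5))
  expect_equal(t_from_summary(same)$value, 0, tolerance = 0)
})

test_that("chi-square of independence matches the direct formula and degenerates correctly", {
  tab <- matrix(c(12, 8, 7, 13), 2, 2)
  res <- chi_square_independence(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$value, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 1, tolerance = 0)

  # proportional rows give exactly zero
  prop <- matrix(c(9, 9, 8, 8, 4, 4), 2, 3)
  res0 <- chi_square_independence(prop)
  expect_equal(res0$value, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1, tolerance = 1e-12)

  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2, 2)),
               "degenerate margins")
  expect_error(chi_square_independence(matrix(c(1.5, 2, 3, 4), 2, 2)),
               "integers")
})

test_that("F and H are invariant to location shifts; H matches the rank oracle under ties", {
  set.seed(107)
  values <- c(stats::rnorm(8), stats::rnorm(8, 1), stats::rnorm(8, 2))
  groups <- rep(1:3, each = 8)
  f1 <- one_way_anova(values, groups)
  f2 <- one_way_anova(values + 100, groups)
  expect_equal(f1$value, f2$value, tolerance = 1e-10)
  h1 <- kruskal_wallis(values, groups)
  h2 <- kruskal_wallis(values + 100, groups)
  expect_equal(h1$value, h2$value, tolerance = 1e-12)

  # tie-corrected H against explicit rank computation
  v <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7, 8, 8)
  g <- rep(c("a", "b", "c"), each = 4)
  h <- kruskal_wallis(v, g)
  r <- rank(v); N <- length(v)
  Rg <- tapply(r, g, sum); ng <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  ties <- table(v)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(h$value, H, tolerance = 1e-12)
})

test_that("Bonferroni post-hocs enumerate all pairs with capped adjusted p-values", {
  set.seed(109)
  values <- c(stats::rnorm(10), stats::rnorm(10, 3), stats::rnorm(10, 0.2))
  groups <- rep(c("HC", "ET1", "ET2"), each = 10)
  ph <- posthoc_bonferroni(values, groups)
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_adjusted, pmin(1, 3 * ph$p_raw), tolerance = 1e-12)
  expect_true(all(ph$p_adjusted <= 1))
  expect_true(all(ph$df == 27))
  # adjustment is monotone in the raw p-value
  o <- order(ph$p_raw)
  expect_true(all(diff(ph$p_adjusted[o]) >= 0))
})

test_that("Dunn post-hoc z-statistics match the direct large-sample rank formula", {
  set.seed(113)
  values <- c(stats::rnorm(7), stats::rnorm(8, 1.5), round(stats::rnorm(6, 1), 1))
  groups <- rep(c("a", "b", "c"), c(7, 8, 6))
  dn <- posthoc_dunn(values, groups)
  expect_equal(nrow(dn), 3L)

  r <- rank(values); N <- length(values)
  ties <- table(values)
  tc <- sum(ties^3 - ties) / (12 * (N - 1))
  rb <- tapply(r, groups, mean); ns <- tapply(r, groups, length)
  z_ab <- (rb[["a"]] - rb[["b"]]) /
    sqrt((N * (N + 1) / 12 - tc) * (1 / ns[["a"]] + 1 / ns[["b"]]))
  row_ab <- dn[dn$group1 == "a" & dn$group2 == "b", ]
  expect_equal(row_ab$z, z_ab, tolerance = 1e-12)
  expect_equal(row_ab$p_adjusted, min(1, 3 * row_ab$p_raw), tolerance = 1e-12)
})

test_that("paired tests handle identity and degenerate difference vectors", {
  x <- c(3, 5, 1, 9, 4)
  t0 <- paired_tests(x, x, "t")
  expect_equal(t0$value, 0, tolerance = 0)
  expect_equal(t0$p_value, 1, tolerance = 0)
  expect_error(paired_tests(x, x, "wilcoxon"), "zero")

  set.seed(127)
  before <- stats::rnorm(10); after <- before + 1 + stats::rnorm(10, sd = 0.3)
  tt <- paired_tests(before, after, "t")
  expect_lt(tt$p_value, 0.01)
  wt <- paired_tests(before, after, "wilcoxon")
  expect_lt(wt$p_value, 0.05)
})

test_that("correlations match their rank/product-moment oracles", {
  set.seed(131)
  x <- stats::rnorm(12)
  expect_equal(correlate(x, x, "pearson")$value, 1, tolerance = 1e-12)

  # Spearman on a 6-point fixture equals rank-then-Pearson
  a <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.3)
  b <- c(2.0, 2.9, 3.8, 4.1, 9.0, 1.1)
  rho <- correlate(a, b, "spearman")$value
  expect_equal(rho, stats::cor(rank(a), rank(b)), tolerance = 1e-12)
})

test_that("normality screening behaves at the null and rejects constants", {
  set.seed(137)
  x <- stats::rnorm(500)
  nt <- normality_tests(x)
  expect_gt(nt$shapiro_wilk$p_value, 0.05)
  expect_gt(nt$kolmogorov_smirnov$p_value, 0.05)
  expect_true(nt$normal)
  expect_error(normality_tests(rep(2, 10)), "constant")

  # Lilliefors statistic equals the empirical-CDF sweep oracle
  y <- c(2.1, 0.4, 1.7, 3.3, 0.9, 2.8, 1.1, 4.0, 2.2, 1.5)
  d <- normality_tests(y)$kolmogorov_smirnov$value
  z <- sort((y - mean(y)) / stats::sd(y))
  p <- stats::pnorm(z); n <- length(y)
  oracle <- max(max(seq_len(n) / n - p), max(p - (seq_len(n) - 1) / n))
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("group comparison routes by normality", {
  # exactly normal score fixtures so the routing is deterministic
  normal <- c(stats::qnorm(stats::ppoints(15)), stats::qnorm(stats::ppoints(15)) + 2)
  res <- compare_groups(normal, rep(c("a", "b"), each = 15))
  set.seed(139)
  expect_true(res$parametric)
  expect_identical(res$omnibus$statistic_name, "F")

  skewed <- c(stats::rexp(15)^3, stats::rexp(15)^3 + 2)
  res2 <- compare_groups(skewed, rep(c("a", "b"), each = 15))
  expect_false(res2$parametric)
  expect_identical(res2$omnibus$statistic_name, "H")
})
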